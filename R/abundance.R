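#' ASV count table with spike-ins, taxonomy and sample metadata
#'
#' @param counts integer matrix, samples x ASVs, with sample IDs as row
#'   names and ASV IDs as column names.
#' @param taxonomy data frame with columns \code{asv}, \code{phylum},
#'   \code{family}, \code{genus}; every non-spike ASV must appear (use
#'   \code{"unassigned"} where taxonomy is unknown).
#' @param meta data frame with one row per sample: \code{sample_id},
#'   \code{soil_id}, \code{native_pH}, \code{perturbed_pH},
#'   \code{treatment} (\code{"chl-"}, \code{"chl+"} or \code{"none"} for
#'   the initial community), \code{nitrate} (\code{"plus"}/\code{"minus"}),
#'   \code{timepoint} (\code{"T0"}/\code{"end"}), \code{replicate}.
#' @param spike_ids character vector of the two internal-standard ASV IDs.
#' @return an object of class \code{count_table}.
#' @export
count_table <- function(counts, taxonomy, meta, spike_ids) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("count_table: counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_table: counts needs sample row names and ASV column names")
  }
  missing_spikes <- setdiff(spike_ids, colnames(counts))
  if (length(missing_spikes) > 0) {
    stop("count_table: spike-in ASVs not found in counts: ",
         paste(missing_spikes, collapse = ", "))
  }
  if (!all(rownames(counts) %in% meta$sample_id)) {
    stop("count_table: samples missing from metadata: ",
         paste(setdiff(rownames(counts), meta$sample_id), collapse = ", "))
  }
  community <- setdiff(colnames(counts), spike_ids)
  missing_tax <- setdiff(community, taxonomy$asv)
  if (length(missing_tax) > 0) {
    stop("count_table: ASVs missing from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "))
  }
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  structure(list(counts = counts, taxonomy = taxonomy, meta = meta,
                 spike_ids = spike_ids),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d ASVs (+%d spike-ins)\n",
              nrow(x$counts), ncol(x$counts) - length(x$spike_ids),
              length(x$spike_ids)))
  invisible(x)
}

#' Normalize counts to absolute abundance with internal-standard spike-ins
#'
#' Merges the two spike-in ASVs into one per-sample reference vector,
#' removes them from the table, and divides every count by the sample's
#' spike total. Resulting values are absolute abundances in multiples of the
#' spike-in DNA quantity; total biomass per sample is the total community
#' read count divided by the spike count. Samples with zero spike counts are
#' flagged and excluded.
#'
#' @param table a \code{count_table}.
#' @param pseudo pseudocount added to every raw count before division
#'   (default 0: plain normalization; differential-enrichment calling uses
#'   its own 0.5 pseudocount).
#' @return an object of class \code{abundance_table} with elements
#'   \code{abs} (samples x ASVs), \code{total_biomass}, \code{spike_counts},
#'   \code{meta}, \code{taxonomy} and a \code{qc} list (Pearson correlation
#'   of the two spike ASVs, per-sample spike fraction, excluded samples).
#' @export
spikein_normalize <- function(table, pseudo = 0) {
  stopifnot(inherits(table, "count_table"))
  spikes <- table$counts[, table$spike_ids, drop = FALSE]
  spike_total <- rowSums(spikes)
  community <- table$counts[, setdiff(colnames(table$counts),
                                      table$spike_ids), drop = FALSE]
  keep <- spike_total > 0
  excluded <- rownames(table$counts)[!keep]
  if (length(excluded) > 0) {
    warning("spikein_normalize: excluding samples with zero spike counts: ",
            paste(excluded, collapse = ", "))
  }
  spike_cor <- if (sum(keep) >= 3) {
    stats::cor(spikes[keep, 1], spikes[keep, 2])
  } else NA_real_
  abs_tab <- (community[keep, , drop = FALSE] + pseudo) / spike_total[keep]
  structure(list(
    abs = abs_tab,
    total_biomass = rowSums(community[keep, , drop = FALSE]) /
      spike_total[keep],
    spike_counts = spike_total[keep],
    meta = table$meta[keep, , drop = FALSE],
    taxonomy = table$taxonomy,
    qc = list(spike_cor = spike_cor,
              spike_fraction = rowSums(spikes) / rowSums(table$counts),
              excluded = excluded)),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa", nrow(x$abs),
              ncol(x$abs)))
  if (!is.null(x$qc$spike_cor)) {
    cat(sprintf(" (spike-in correlation %.2f)", x$qc$spike_cor))
  }
  cat("\n")
  invisible(x)
}

#' Aggregate an abundance table to a taxonomic level
#'
#' Sums absolute abundances over all ASVs sharing the same label at the
#' requested level; ASVs without an assignment are pooled into
#' \code{"unassigned"}.
#'
#' @param abund an \code{abundance_table} at ASV level.
#' @param level one of \code{"phylum"}, \code{"family"}, \code{"genus"}.
#' @return an \code{abundance_table} whose columns are taxa at that level.
#' @export
aggregate_taxon <- function(abund, level = c("phylum", "family", "genus")) {
  stopifnot(inherits(abund, "abundance_table"))
  level <- match.arg(level)
  labels <- abund$taxonomy[[level]][match(colnames(abund$abs),
                                          abund$taxonomy$asv)]
  labels[is.na(labels) | labels == ""] <- "unassigned"
  groups <- unique(labels)
  agg <- vapply(groups, function(g) {
    rowSums(abund$abs[, labels == g, drop = FALSE])
  }, numeric(nrow(abund$abs)))
  agg <- matrix(agg, nrow = nrow(abund$abs),
                dimnames = list(rownames(abund$abs), groups))
  out <- abund
  out$abs <- agg
  out$level <- level
  out
}

# Build the per-sample condition key used for chl-/chl+ pairing.
.cond_key <- function(meta) {
  paste(meta$soil_id, meta$perturbed_pH, sep = "|")
}

#' Growth folds: log-ratio of chl- to chl+ endpoint abundance
#'
#' For each taxon and condition, the growth fold is
#' \eqn{g = \log(Abs^- + 10^{-3}) - \log(Abs^+ + 10^{-3})} (natural log),
#' computed per replicate pair (rep1-rep1, ...), summarized by the median
#' across pairs, and clipped below at zero: the chloramphenicol arm is the
#' reference, so positive folds isolate growth-mediated abundance change.
#'
#' @param abund an \code{abundance_table} (any taxonomic level).
#' @param pseudo pseudocount on the absolute-abundance scale (default 1e-3).
#' @param clip set negative folds to zero (default TRUE).
#' @return an object of class \code{fold_table}: list with \code{folds}
#'   (taxa x conditions matrix) and \code{conditions} (data frame of
#'   soil_id, perturbed_pH, native_pH).
#' @export
growth_folds <- function(abund, pseudo = 1e-3, clip = TRUE) {
  stopifnot(inherits(abund, "abundance_table"))
  m <- abund$meta
  end_nitrate <- m$timepoint == "end" & m$nitrate == "plus"
  conds <- unique(.cond_key(m[end_nitrate, , drop = FALSE]))
  fold_cols <- list()
  cond_rows <- list()
  for (cond in conds) {
    sel <- end_nitrate & .cond_key(m) == cond
    minus <- which(sel & m$treatment == "chl-")
    plus <- which(sel & m$treatment == "chl+")
    reps <- intersect(m$replicate[minus], m$replicate[plus])
    if (length(minus) == 0 || length(plus) == 0 || length(reps) == 0) {
      warning("growth_folds: condition ", cond,
              " lacks a matched chl-/chl+ arm; dropped")
      next
    }
    per_rep <- vapply(reps, function(r) {
      i <- minus[m$replicate[minus] == r][1]
      j <- plus[m$replicate[plus] == r][1]
      log(abund$abs[i, ] + pseudo) - log(abund$abs[j, ] + pseudo)
    }, numeric(ncol(abund$abs)))
    g <- apply(matrix(per_rep, ncol = length(reps)), 1, stats::median)
    if (clip) g <- pmax(g, 0)
    fold_cols[[cond]] <- g
    i0 <- minus[1]
    cond_rows[[cond]] <- data.frame(soil_id = m$soil_id[i0],
                                    perturbed_pH = m$perturbed_pH[i0],
                                    native_pH = m$native_pH[i0])
  }
  if (length(fold_cols) == 0) stop("growth_folds: no pairable conditions")
  folds <- do.call(cbind, fold_cols)
  rownames(folds) <- colnames(abund$abs)
  structure(list(folds = folds,
                 conditions = do.call(rbind, cond_rows),
                 type = "growth"),
            class = "fold_table")
}

#' Survival folds: log-ratio of chl+ endpoint to initial (T0) abundance
#'
#' Computed with the same pseudocount as growth folds but not clipped:
#' declines (negative folds) are the signal, a proxy for death in the
#' absence of growth.
#'
#' @param abund an \code{abundance_table}.
#' @param pseudo pseudocount on the absolute-abundance scale (default 1e-3).
#' @return a \code{fold_table} with unclipped folds.
#' @export
survival_folds <- function(abund, pseudo = 1e-3) {
  stopifnot(inherits(abund, "abundance_table"))
  m <- abund$meta
  is_t0 <- m$timepoint == "T0"
  end_plus <- m$timepoint == "end" & m$treatment == "chl+" &
    m$nitrate == "plus"
  conds <- unique(.cond_key(m[end_plus, , drop = FALSE]))
  fold_cols <- list()
  cond_rows <- list()
  for (cond in conds) {
    sel <- which(end_plus & .cond_key(m) == cond)
    soil <- m$soil_id[sel[1]]
    t0 <- which(is_t0 & m$soil_id == soil)
    if (length(t0) == 0) {
      warning("survival_folds: soil ", soil, " has no T0 samples; dropped")
      next
    }
    reps <- intersect(m$replicate[sel], m$replicate[t0])
    if (length(reps) == 0) reps <- m$replicate[sel]
    per_rep <- vapply(reps, function(r) {
      i <- sel[m$replicate[sel] == r][1]
      j0 <- t0[m$replicate[t0] == r]
      j <- if (length(j0) > 0) j0[1] else t0[1]
      log(abund$abs[i, ] + pseudo) - log(abund$abs[j, ] + pseudo)
    }, numeric(ncol(abund$abs)))
    fold_cols[[cond]] <- apply(matrix(per_rep, ncol = length(reps)), 1,
                               stats::median)
    cond_rows[[cond]] <- data.frame(soil_id = soil,
                                    perturbed_pH = m$perturbed_pH[sel[1]],
                                    native_pH = m$native_pH[sel[1]])
  }
  if (length(fold_cols) == 0) stop("survival_folds: no pairable conditions")
  folds <- do.call(cbind, fold_cols)
  rownames(folds) <- colnames(abund$abs)
  structure(list(folds = folds,
                 conditions = do.call(rbind, cond_rows),
                 type = "survival"),
            class = "fold_table")
}

#' @export
print.fold_table <- function(x, ...) {
  cat(sprintf("fold_table (%s): %d taxa x %d conditions\n", x$type,
              nrow(x$folds), ncol(x$folds)))
  invisible(x)
}
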