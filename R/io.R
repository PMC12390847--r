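#' Read paired nitrate time series from a long-format table
#'
#' Expects columns \code{soil_id}, \code{perturbed_pH}, \code{treatment}
#' (\code{"chl-"}/\code{"chl+"}), \code{replicate}, \code{time} (days) and
#' \code{nitrate} (mM); tab or comma separation is auto-detected. Rows are
#' paired by (soil, pH, replicate); conditions with only one arm are
#' reported and skipped.
#'
#' @param path file path.
#' @return a list of \code{nitrate_pair} objects.
#' @export
read_nitrate_series <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("soil_id", "perturbed_pH", "treatment", "replicate",
            "time", "nitrate")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("read_nitrate_series: missing columns: ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$soil_id, df$perturbed_pH, df$replicate, sep = "|")
  pairs <- list()
  for (k in unique(key)) {
    d <- df[key == k, , drop = FALSE]
    dm <- d[d$treatment == "chl-", , drop = FALSE]
    dp <- d[d$treatment == "chl+", , drop = FALSE]
    if (nrow(dm) == 0 || nrow(dp) == 0) {
      warning("read_nitrate_series: condition ", k,
              " has a single arm; skipped")
      next
    }
    dm <- dm[order(dm$time), ]; dp <- dp[order(dp$time), ]
    pairs[[length(pairs) + 1L]] <- nitrate_pair(
      dm$time, dm$nitrate, dp$time, dp$nitrate,
      soil_id = d$soil_id[1], perturbed_pH = d$perturbed_pH[1],
      replicate = d$replicate[1])
  }
  pairs
}

#' Write nitrate pairs to a long-format TSV
#'
#' @param pairs list of \code{nitrate_pair}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_nitrate_series <- function(pairs, path) {
  rows <- lapply(pairs, function(p) {
    data.frame(soil_id = p$soil_id, perturbed_pH = p$perturbed_pH,
               treatment = rep(c("chl-", "chl+"),
                               c(length(p$t_minus), length(p$t_plus))),
               replicate = p$replicate,
               time = c(p$t_minus, p$t_plus),
               nitrate = c(p$a_minus, p$a_plus))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count table from delimited files
#'
#' Counts may be a dense TSV (samples in rows, first column the sample ID)
#' or a Matrix Market triplet file (suffix \code{.mtx}) accompanied by row
#' and column name files (\code{<stem>.rows}, \code{<stem>.cols}, one name
#' per line). Taxonomy and metadata are TSVs keyed by \code{asv} and
#' \code{sample_id}.
#'
#' @param counts_path counts file.
#' @param taxonomy_path taxonomy TSV (columns asv, phylum, family, genus).
#' @param meta_path sample metadata TSV.
#' @param spike_ids the two internal-standard ASV IDs.
#' @return a \code{count_table}.
#' @export
read_count_table <- function(counts_path, taxonomy_path, meta_path,
                             spike_ids) {
  if (grepl("\\.mtx$", counts_path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("read_count_table: the Matrix package is required for .mtx input")
    }
    m <- as.matrix(Matrix::readMM(counts_path))
    stem <- sub("\\.mtx$", "", counts_path)
    rownames(m) <- readLines(paste0(stem, ".rows"))
    colnames(m) <- readLines(paste0(stem, ".cols"))
    counts <- m
  } else {
    df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE)
    counts <- as.matrix(df)
  }
  taxonomy <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  count_table(counts = counts, taxonomy = taxonomy, meta = meta,
              spike_ids = spike_ids)
}

#' Write a count table to delimited files
#'
#' @param table a \code{count_table}.
#' @param dir output directory (created if missing).
#' @param stem file stem (default \code{"counts"}).
#' @return paths of the three files written, invisibly.
#' @export
write_count_table <- function(table, dir, stem = "counts") {
  stopifnot(inherits(table, "count_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cp <- file.path(dir, paste0(stem, ".tsv"))
  tp <- file.path(dir, paste0(stem, "_taxonomy.tsv"))
  mp <- file.path(dir, paste0(stem, "_meta.tsv"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, cp, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(table$taxonomy, tp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$meta, mp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(counts = cp, taxonomy = tp, meta = mp))
}

#' Run the full regime analysis pipeline
#'
#' Wires the stages end to end: fit the consumer-resource model to every
#' replicate pair, aggregate to condition medians, classify regimes,
#' spike-normalize the count table, compute phylum growth folds, call
#' enriched ASVs with the empirical noise model, decompose the growth
#' matrix by rank-2 NMF, and (when enough resurgent-growth samples exist)
#' fit the native-pH LASSO. Metabolite-only runs skip the sequencing
#' stages.
#'
#' @param pairs list of \code{nitrate_pair} (metabolite stage input).
#' @param table optional \code{count_table} (sequencing stage input).
#' @param gamma,K_A,K_C_tilde fixed fitting parameters.
#' @param thresholds \code{regime_thresholds}.
#' @param alpha enrichment significance level.
#' @param n_starts multistart count per fit.
#' @param seed integer seed.
#' @param fallback_noise optional \code{noise_model} for sparse conditions.
#' @return a list of stage outputs plus a \code{manifest} of row counts and
#'   timings.
#' @export
run_regime_pipeline <- function(pairs, table = NULL, gamma = 4.8,
                                K_A = 0.01, K_C_tilde = 0.01,
                                thresholds = regime_thresholds(),
                                alpha = 0.05, n_starts = 4, seed = 1,
                                fallback_noise = NULL) {
  manifest <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    manifest[[stage]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    val
  }

  fits <- tick("fit", fit_crm_panel(pairs, gamma = gamma, K_A = K_A,
                                    K_C_tilde = K_C_tilde,
                                    n_starts = n_starts, seed = seed))
  manifest$fit$rows <- nrow(fits$fits)

  cond <- fits$conditions
  calls <- classify_regime(cond$x0_tilde, cond$gammaC0_tilde, thresholds)
  cond$regime <- calls$label
  cond$ambiguous_quadrant <- calls$ambiguous_quadrant
  out <- list(fits = fits$fits, conditions = cond, manifest = manifest)

  if (is.null(table)) return(out)

  abund <- tick("abundance", spikein_normalize(table))
  phylum <- aggregate_taxon(abund, "phylum")
  gf <- tick("folds", growth_folds(phylum))
  sf <- tryCatch(survival_folds(phylum), error = function(e) NULL)

  regime_map <- stats::setNames(cond$regime,
                                paste(cond$soil_id, cond$perturbed_pH,
                                      sep = "|"))
  enr <- tick("enrichment",
              enrichment_analysis(table, regime_by_condition = regime_map,
                                  alpha = alpha,
                                  fallback_model = fallback_noise))

  G <- build_growth_matrix(gf)
  nmf <- tick("nmf", nmf_decompose(G, rank = 2, seed = seed))

  regression <- NULL
  r3 <- enr$call$by_regime[["III"]]
  if (!is.null(r3) && length(r3) > 0) {
    m <- table$meta
    iii_conds <- names(regime_map)[regime_map == "III"]
    sel <- m$timepoint == "end" & m$nitrate == "plus" &
      m$treatment == "chl-" & .cond_key(m) %in% iii_conds
    samples <- m$sample_id[sel]
    if (length(unique(m$soil_id[sel])) >= 3) {
      pm <- build_presence_matrix(table, enriched = r3, samples = samples,
                                  level = "family", rel_thresh = 0)
      regression <- tick("regression", list(
        fit = fit_lasso_cv(pm, seed = seed),
        loso = loso_predict(pm, seed = seed)))
      regression$r2_loso <- r2_by_soil(regression$loso$predicted,
                                       regression$loso$native_pH,
                                       regression$loso$soil_id)
    }
  }

  out$abundance <- abund
  out$growth_folds <- gf
  out$survival_folds <- sf
  out$enrichment <- enr$call
  out$nmf <- nmf
  out$regression <- regression
  out$manifest <- manifest
  out
}
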