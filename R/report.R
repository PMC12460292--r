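#' Full agreement report for a disc sample table
#'
#' Computes the complete validation suite from paired TLS-estimated and
#' water-displacement reference volumes: overall and per-species error
#' metrics (R^2, RMSE, RE, Bias, rRMSE), Bland-Altman limits of agreement,
#' concordance correlation, gauge repeatability from the reference
#' replicates, a Kruskal-Wallis test of the error variable across species,
#' and all pairwise Mann-Whitney comparisons with raw and Holm-adjusted p
#' values. Species with fewer than 2 samples are skipped from the per-species
#' block (with a warning) but kept in the overall metrics.
#'
#' @param samples a `disc_samples` data.frame (see [read_samples_table()]).
#' @param conventions an [agreement_conventions()].
#' @return object of class `agreement_report` (JSON-serialisable via
#'   [report_to_json()]).
#' @export
build_report <- function(samples, conventions = agreement_conventions()) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 2L) stop("at least 2 samples required")
  obs <- samples$reference_volume
  est <- samples$estimated_volume

  overall <- c(regression_metrics(obs, est),
               bland_altman(obs, est, conventions)[
                 c("mean_diff", "sd_diff", "uloa", "lloa")],
               list(ccc = tryCatch(ccc(obs, est, conventions),
                                   error = function(e) NA_real_)))

  reps <- as.matrix(samples[, intersect(c("rep1", "rep2", "rep3"), names(samples))])
  grr_res <- tryCatch(grr(reps), error = function(e) NULL)

  species <- unique(samples$species)
  per_species <- list()
  for (sp in species) {
    idx <- samples$species == sp
    if (sum(idx) < 2L) {
      warning(sprintf("species '%s' has < 2 samples; skipped from per-species metrics", sp))
      next
    }
    per_species[[sp]] <- c(
      regression_metrics(obs[idx], est[idx]),
      bland_altman(obs[idx], est[idx], conventions)[
        c("mean_diff", "sd_diff", "uloa", "lloa")],
      list(ccc = tryCatch(ccc(obs[idx], est[idx], conventions),
                          error = function(e) NA_real_)))
  }

  d <- if (conventions$diff_direction == "est_minus_obs") est - obs else obs - est
  groups <- split(d, samples$species)
  groups <- groups[lengths(groups) > 0]
  kw <- if (length(groups) >= 2L)
    tryCatch(kruskal_wallis(groups, conventions),
             error = function(e) list(H = NA_real_, p = NA_real_,
                                      note = conditionMessage(e)))
  else NULL

  pairwise <- NULL
  if (length(groups) >= 2L) {
    combos <- utils::combn(names(groups), 2)
    pairwise <- data.frame(species_a = combos[1, ], species_b = combos[2, ],
                           U = NA_real_, p = NA_real_,
                           stringsAsFactors = FALSE)
    for (i in seq_len(ncol(combos))) {
      mw <- mann_whitney_u(groups[[combos[1, i]]], groups[[combos[2, i]]],
                           conventions)
      pairwise$U[i] <- mw$U
      pairwise$p[i] <- mw$p
    }
    pairwise$p_holm <- p.adjust(pairwise$p, method = "holm")
  }

  structure(list(n = nrow(samples),
                 conventions = conventions,
                 overall = overall,
                 grr = grr_res,
                 per_species = per_species,
                 kw = kw,
                 pairwise = pairwise,
                 differences = data.frame(species = samples$species, diff = d,
                                          mean = (obs + est) / 2)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 4, ...) {
  cat(sprintf("Agreement report (n = %d; diff = %s, ccc variances = %s)\n",
              x$n, x$conventions$diff_direction, x$conventions$variance_mode))
  ov <- x$overall
  cat(sprintf("  R^2 = %.*g  RMSE = %.*g cm3  RE = %.*g  Bias = %.*g cm3  rRMSE = %.*g%%\n",
              digits, ov$r_squared, digits, ov$rmse, digits, ov$re,
              digits, ov$bias, digits, ov$rrmse))
  cat(sprintf("  Bland-Altman: mean diff = %.*g, s = %.*g, LoA [%.*g, %.*g] cm3\n",
              digits, ov$mean_diff, digits, ov$sd_diff,
              digits, ov$lloa, digits, ov$uloa))
  cat(sprintf("  CCC = %.*g", digits, ov$ccc))
  if (!is.null(x$grr)) cat(sprintf("  GRR = %.*g%%", digits, x$grr$grr_percent))
  cat("\n")
  if (length(x$per_species)) {
    cat("  Per species:\n")
    for (sp in names(x$per_species)) {
      m <- x$per_species[[sp]]
      cat(sprintf("    %-24s n = %3d  RMSE = %8.3f  rRMSE = %6.2f%%  bias = %8.3f\n",
                  sp, m$n, m$rmse, m$rrmse, m$bias))
    }
  }
  if (!is.null(x$kw) && is.finite(x$kw$H))
    cat(sprintf("  Kruskal-Wallis: H = %.*g, p = %.3g\n", digits, x$kw$H, x$kw$p))
  else if (!is.null(x$kw))
    cat("  Kruskal-Wallis: not applicable (degenerate input)\n")
  if (!is.null(x$pairwise)) {
    cat("  Pairwise Mann-Whitney:\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: U = %g, p = %.3g (holm %.3g)\n",
                  x$pairwise$species_a[i], x$pairwise$species_b[i],
                  x$pairwise$U[i], x$pairwise$p[i], x$pairwise$p_holm[i]))
  }
  invisible(x)
}

#' Serialise an agreement report to JSON
#' @param report an `agreement_report`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- unclass(report)
  payload$conventions <- unclass(payload$conventions)
  payload$differences <- NULL
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Bland-Altman plot of an agreement report
#'
#' Paired differences against paired means, with the mean difference and the
#' 95% limits of agreement.
#'
#' @param x an `agreement_report`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the report.
#' @export
plot.agreement_report <- function(x, ...) {
  ov <- x$overall
  d <- x$differences
  graphics::plot(d$mean, d$diff,
                 ylim = range(c(d$diff, ov$uloa, ov$lloa)),
                 xlab = "pair mean (cm3)", ylab = "difference (cm3)",
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = ov$mean_diff, col = "red")
  graphics::abline(h = c(ov$lloa, ov$uloa), col = "darkgreen", lty = 2)
  invisible(x)
}
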