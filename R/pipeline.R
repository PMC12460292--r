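#' Run the full disc-volume workflow
#'
#' Wires the modules into the end-to-end workflow: (simulate |) fill ->
#' normals -> reconstruct -> volume per disc, then joins the volumes with the
#' reference measurements and builds the agreement report. A disc whose
#' reconstruction fails (e.g. not watertight) is excluded from the report and
#' itemised with its reason; per-disc failures never abort the batch.
#'
#' @param config a named list or the path of a YAML file with blocks:
#'   \describe{
#'     \item{simulation}{`list(n, seed, ...)` — `...` passed to
#'       [disc_spec()]; discs are generated with seeds `seed + 0:(n-1)` and
#'       their true volumes used as references; mutually exclusive with
#'       `inputs`.}
#'     \item{inputs}{list of `list(path, unit, id)` point cloud files.}
#'     \item{references}{path of a sample CSV (see [read_samples_table()])
#'       joined by id; required with `inputs`.}
#'     \item{fill}{`list(dedupe_tol)`.}
#'     \item{normals}{`list(k, method, graph_k)`.}
#'     \item{reconstruct}{arguments of [reconstruction_settings()].}
#'     \item{conventions}{arguments of [agreement_conventions()].}
#'     \item{out_dir}{optional output directory: writes `volumes.csv`,
#'       `report.json` and `manifest.json`.}
#'   }
#' @return list of class `disc_pipeline_result` with `volumes` (per-disc
#'   data.frame incl. status), `report` (an `agreement_report` or NULL),
#'   `excluded`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  fill_cfg <- config$fill %||% list()
  nrm_cfg <- config$normals %||% list()
  rec_cfg <- config$reconstruct %||% list()
  settings <- do.call(reconstruction_settings, rec_cfg)
  conventions <- do.call(agreement_conventions, config$conventions %||% list())

  discs <- list()
  refs <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    # YAML 1.1 parses a bare key `n` as a boolean; map it back
    names(sim)[names(sim) == "FALSE"] <- "n"
    n <- sim$n %||% 5L
    seed0 <- sim$seed %||% 1L
    spec_args <- sim[setdiff(names(sim), c("n", "seed"))]
    # scalar disc parameters given as length-n vectors vary per disc
    per_disc <- setdiff(names(spec_args), "stations")
    for (i in seq_len(n)) {
      sd_i <- seed0 + i - 1L
      args_i <- spec_args
      for (nm in per_disc)
        if (length(args_i[[nm]]) > 1L)
          args_i[[nm]] <- args_i[[nm]][[(i - 1L) %% length(args_i[[nm]]) + 1L]]
      disc <- generate_disc(do.call(disc_spec, c(args_i, list(seed = sd_i))))
      discs[[disc$cloud$id]] <- disc$cloud
      refs <- rbind(refs, data.frame(
        id = disc$cloud$id, species = "synthetic",
        rep1 = disc$true_volume, rep2 = NA_real_, rep3 = NA_real_,
        reference_volume = disc$true_volume, stringsAsFactors = FALSE))
    }
  } else if (!is.null(config$inputs)) {
    for (inp in config$inputs) {
      cl <- read_point_cloud(inp$path, unit = inp$unit %||% "m",
                             id = inp$id %||% basename(inp$path))
      discs[[cl$id]] <- cl
    }
    if (is.null(config$references))
      stop("config$references is required with config$inputs")
    rtab <- read.csv(config$references, stringsAsFactors = FALSE)
    for (r in c("rep2", "rep3")) if (!r %in% names(rtab)) rtab[[r]] <- NA_real_
    rtab$reference_volume <- rowMeans(rtab[, c("rep1", "rep2", "rep3")],
                                      na.rm = TRUE)
    refs <- rtab
  } else {
    stop("config must contain a 'simulation' or an 'inputs' block")
  }

  results <- data.frame(id = names(discs), species = NA_character_,
                        status = "ok", volume_cm3 = NA_real_,
                        reference_cm3 = NA_real_, rel_error = NA_real_,
                        reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(discs)) {
    cl <- discs[[i]]
    res <- tryCatch({
      filled <- fill_bottom(cl, dedupe_tol = fill_cfg$dedupe_tol %||% 0)
      oc <- estimate_normals(filled$complete, k = nrm_cfg$k %||% 6L,
                             method = nrm_cfg$method %||% "quadratic")
      oc <- orient_normals_mst(oc, k_graph = nrm_cfg$graph_k %||% 10L)
      mesh <- reconstruct_surface(oc, settings)
      as.numeric(divergence_volume(mesh))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      results$status[i] <- "excluded"
      results$reason[i] <- conditionMessage(res)
    } else {
      results$volume_cm3[i] <- res
    }
  }
  m <- match(results$id, refs$id)
  results$species <- refs$species[m] %||% NA_character_
  results$reference_cm3 <- refs$reference_volume[m]
  results$rel_error <- (results$volume_cm3 - results$reference_cm3) /
    results$reference_cm3

  ok <- results$status == "ok" & is.finite(results$reference_cm3)
  if (!any(ok)) stop("no disc survived the pipeline; nothing to report")
  report <- NULL
  if (sum(ok) >= 2L) {
    samples <- data.frame(id = results$id[ok], species = results$species[ok],
                          estimated_volume = results$volume_cm3[ok],
                          rep1 = refs$rep1[m][ok], rep2 = refs$rep2[m][ok],
                          rep3 = refs$rep3[m][ok],
                          reference_volume = results$reference_cm3[ok],
                          stringsAsFactors = FALSE)
    class(samples) <- c("disc_samples", "data.frame")
    report <- suppressWarnings(build_report(samples, conventions))
  }

  manifest <- list(
    tool = "disctls", version = as.character(utils::packageVersion("disctls")),
    subcommand = "pipeline",
    config = config[setdiff(names(config), "out_dir")],
    n_discs = length(discs), n_ok = sum(results$status == "ok"),
    excluded = results$id[results$status != "ok"],
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results[, setdiff(names(results), "reason")],
              file.path(config$out_dir, "volumes.csv"), row.names = FALSE,
              quote = FALSE)
    if (!is.null(report))
      report_to_json(report, file.path(config$out_dir, "report.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null"),
               file.path(config$out_dir, "manifest.json"))
  }
  structure(list(volumes = results, report = report,
                 excluded = results[results$status != "ok",
                                    c("id", "reason"), drop = FALSE],
                 manifest = manifest),
            class = "disc_pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.disc_pipeline_result <- function(x, ...) {
  cat(sprintf("disc_pipeline_result: %d disc(s), %d ok, %d excluded\n",
              nrow(x$volumes), sum(x$volumes$status == "ok"),
              sum(x$volumes$status != "ok")))
  print(x$volumes[, c("id", "species", "status", "volume_cm3",
                      "reference_cm3", "rel_error")])
  invisible(x)
}
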