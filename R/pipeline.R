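#' Run configuration for the end-to-end pipeline
#'
#' A configuration holds either an `input_dir` (quantify existing images)
#' or a `simulate` block (generate a cohort), plus binarization and
#' Phansalkar parameters and an output directory. Configurations are plain
#' JSON-compatible lists and can be loaded from a JSON file.
#'
#' @param x path to a JSON config file, or a named list.
#' @return Validated config list of class `octa_config`.
#' @export
octa_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else x
  has_in <- !is.null(cfg$input_dir)
  has_sim <- !is.null(cfg$simulate)
  if (has_in == has_sim)
    stop_octa("config must contain exactly one of `input_dir` / `simulate`")
  if (has_sim) {
    sim <- cfg$simulate
    if (is.null(sim$n_eyes) || sim$n_eyes < 2)
      stop_octa("`simulate$n_eyes` must be >= 2")
  }
  bp <- cfg$binarization %||% list()
  cfg$bin_params <- do.call(binarization_params, bp)
  pp <- cfg$phansalkar %||% list()
  cfg$phan_params <- do.call(phansalkar_params, pp)
  cfg$output_dir <- cfg$output_dir %||% "."
  class(cfg) <- "octa_config"
  cfg
}

resolve_cohort_from_config <- function(cfg, seed = NULL) {
  sim <- cfg$simulate
  seed <- seed %||% sim$seed %||% 1L
  image_size <- sim$image_size %||% 304
  nv1 <- do.call(noise_model, as.list(sim$noise_v1 %||% list(n_volumes = 1)))
  nv4 <- do.call(noise_model, as.list(sim$noise_v4 %||% list(n_volumes = 4)))
  generate_cohort(sim$n_eyes, noise_v1 = nv1, noise_v4 = nv4,
                  seed = as.integer(seed),
                  jitter = sim$jitter %||% 0.10, image_size = image_size)
}

#' Simulate a cohort and write it as an image tree
#'
#' Writes `<out>/images/<eyeID>_<plexus>_<mode>.tif`, a ground-truth JSON
#' sidecar per eye under `<out>/truth/`, and a `manifest.csv` listing every
#' image file. Re-running with the same seed produces byte-identical
#' output.
#'
#' @param config an [octa_config()] (or path/list coercible to one) with a
#'   `simulate` block.
#' @param out output directory (defaults to the config's `output_dir`).
#' @param seed optional master-seed override.
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(config, out = NULL, seed = NULL) {
  cfg <- if (inherits(config, "octa_config")) config else octa_config(config)
  if (is.null(cfg$simulate)) stop_octa("config has no `simulate` block")
  out <- out %||% cfg$output_dir
  img_dir <- file.path(out, "images"); truth_dir <- file.path(out, "truth")
  ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) ||
    dir.exists(img_dir)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir) || !dir.exists(truth_dir))
    stop_octa("cannot create output directory under ", out)
  coh <- resolve_cohort_from_config(cfg, seed)
  manifest <- list()
  for (eye in coh$eyes) {
    truth <- lapply(eye$truth, function(gt) {
      list(plexus = gt$plexus, true_pd = gt$true_pd, true_vld = gt$true_vld,
           true_vdi = gt$true_vdi, true_fd = gt$true_fd)
    })
    jsonlite::write_json(truth, file.path(truth_dir, paste0(eye$eye_id, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (img in eye$images) {
      fname <- sprintf("%s_%s_%s.tif", img$eye_id, img$plexus,
                       img$acquisition_mode)
      write_octa_image(img, file.path(img_dir, fname))
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = file.path("images", fname), eye_id = img$eye_id,
        plexus = img$plexus, mode = img$acquisition_mode,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Quantify a directory of en face images
#'
#' Reads every image listed in `manifest.csv` (or, absent a manifest, every
#' `.tif`/`.tiff`/`.png` under `images/` or the directory itself, with
#' metadata parsed from `<eyeID>_<plexus>_<mode>` file names) and computes
#' the per-image metrics. Unreadable or degenerate images are skipped with
#' a warning; the run fails only if no image can be processed.
#'
#' @param input_dir directory containing the images (and optionally
#'   `manifest.csv`).
#' @param out_csv path of the metrics CSV to write (NULL = don't write).
#' @param bin_params,phan_params processing parameters.
#' @return The metrics data frame; attribute `"n_failed"` counts skipped
#'   images.
#' @export
run_quantify <- function(input_dir, out_csv = NULL,
                         bin_params = binarization_params(),
                         phan_params = phansalkar_params()) {
  man_path <- file.path(input_dir, "manifest.csv")
  files <- if (file.exists(man_path)) {
    file.path(input_dir, read.csv(man_path, stringsAsFactors = FALSE)$file)
  } else {
    roots <- c(file.path(input_dir, "images"), input_dir)
    root <- roots[dir.exists(roots)][1]
    list.files(root, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
               full.names = TRUE)
  }
  if (length(files) == 0) stop_octa("no images found under ", input_dir)
  rows <- list(); failed <- 0L
  for (f in files) {
    row <- tryCatch({
      img <- read_octa_image(f)
      quantify_image(img, bin_params, phan_params)
    }, error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(row)) failed <- failed + 1L else rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) stop_octa("no parsable images under ", input_dir)
  metrics <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(out_csv)) write.csv(metrics, out_csv, row.names = FALSE)
  attr(metrics, "n_failed") <- failed
  metrics
}

#' Build and write the cohort agreement report
#'
#' @param metrics a metrics data frame or path to a metrics CSV (from
#'   [run_quantify()] / [quantify_cohort()]).
#' @param out_dir directory for `report.csv`, `report.json` and
#'   `ba_plot_data.csv` (NULL = don't write).
#' @return The [build_agreement_report()] object, invisibly after printing
#'   the summary table.
#' @export
run_report <- function(metrics, out_dir = NULL) {
  if (is.character(metrics)) metrics <- read.csv(metrics, stringsAsFactors = FALSE)
  rep <- build_agreement_report(metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep$table, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(rep$table, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    write.csv(rep$ba_plot_data, file.path(out_dir, "ba_plot_data.csv"),
              row.names = FALSE)
  }
  print(rep)
  invisible(rep)
}
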