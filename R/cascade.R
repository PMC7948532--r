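#' Configuration for an end-to-end cascade run
#'
#' Bundles every knob of the pipeline: phantom generation, surrogate
#' localization, resolution mapping, contour parameters, and output. The
#' whole run is a pure function of this object, so two runs from one
#' config are byte-identical.
#'
#' @param n Number of seeded phantom cases.
#' @param image_size Segmentation-frame side in pixels (default 512).
#' @param low_size Localization-frame side (default 128); must divide
#'   `image_size`.
#' @param rician_sigma Phantom noise scale.
#' @param jitter_frac,margin_frac Surrogate-localizer perturbation and
#'   box expansion (see [oracle_localizer()]).
#' @param method `"chanvese"`, `"prewitt"`, or both (for
#'   [compare_methods()]).
#' @param params [cv_params()] for the contour.
#' @param enhance_method Passed to [enhance()].
#' @param prewitt_threshold Threshold fraction for the gradient baseline.
#' @param seed Global integer seed; case `i` derives its seeds from
#'   `seed + i`.
#' @param outdir Optional directory; when given, images, masks and a
#'   summary CSV/JSON are written there.
#' @return A `run_config` object.
#' @export
run_config <- function(n = 20L, image_size = 512L, low_size = 128L,
                       rician_sigma = 0.05, jitter_frac = 0.1,
                       margin_frac = 0.15,
                       method = c("chanvese", "prewitt"),
                       params = cv_params(), enhance_method = "both",
                       prewitt_threshold = 0.3, seed = 1L,
                       outdir = NULL) {
  if (image_size %% low_size != 0) stop("low_size must divide image_size")
  structure(list(n = as.integer(n), image_size = as.integer(image_size),
                 low_size = as.integer(low_size),
                 rician_sigma = rician_sigma, jitter_frac = jitter_frac,
                 margin_frac = margin_frac, method = method,
                 params = params, enhance_method = enhance_method,
                 prewitt_threshold = prewitt_threshold,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# Draw a valid tumor geometry for case seed: center in an annulus around
# the slice center (clear of the ventricle lobes), random semi-axes and
# orientation. Retries until the phantom invariants hold.
sample_phantom_spec <- function(config, case_seed) {
  n <- config$image_size
  for (attempt in 1:50) {
    spec <- with_seed(case_seed + 1000L * attempt, {
      rad <- stats::runif(1L, 0.16, 0.26) * n
      ang <- stats::runif(1L, 0, 2 * pi)
      phantom_spec(
        image_size = n,
        tumor_center = c(n / 2 + rad * sin(ang), n / 2 + rad * cos(ang)),
        tumor_axes = c(stats::runif(1L, 0.07, 0.10),
                       stats::runif(1L, 0.05, 0.075)) * n,
        tumor_angle = stats::runif(1L, 0, pi),
        rician_sigma = config$rician_sigma,
        class_label = if (stats::runif(1L) < 0.5) "meningioma" else "glioma",
        seed = case_seed
      )
    })
    ok <- tryCatch({ generate_phantom(spec); TRUE },
                   error = function(e) FALSE)
    if (ok) return(spec)
  }
  stop("could not place a valid tumor after 50 attempts")
}

run_one_case <- function(config, case_seed, method) {
  spec <- sample_phantom_spec(config, case_seed)
  ph <- generate_phantom(spec)
  res <- resolution_pair(config$low_size, config$image_size)

  # localize in the low-resolution frame, as the detector would
  box_lo <- map_box(ph$truth$box, res, "down")
  truth_lo <- list(box = box_lo,
                   mask = matrix(FALSE, config$low_size, config$low_size))
  det_lo <- oracle_localizer(truth_lo, config$jitter_frac,
                             config$margin_frac, seed = case_seed)
  det_hi <- map_box(det_lo, res, "up")

  seg <- segment_tumor(ph$image, det_hi, config$params, method,
                       config$enhance_method, config$prewitt_threshold,
                       return_details = TRUE)
  rep <- metrics_report(seg$mask, ph$truth$mask,
                        params = list(seed = case_seed, method = method))
  trace <- if (!is.null(seg$state)) seg$state$energy_trace else numeric(0)
  list(seed = case_seed, method = method, label = ph$truth$label,
       box = seg$box, confidence = det_lo$confidence,
       metrics = rep,
       energy_initial = if (length(trace)) trace[1L] else NA_real_,
       energy_final = if (length(trace)) trace[length(trace)] else NA_real_,
       image = ph$image, mask = seg$mask, truth = ph$truth)
}

case_row <- function(case) {
  m <- case$metrics
  data.frame(seed = case$seed, method = case$method, label = case$label,
             confidence = case$confidence,
             r0 = case$box$r0, c0 = case$box$c0,
             r1 = case$box$r1, c1 = case$box$c1,
             dice = m$dice, rand_index = m$rand_index, voi = m$voi,
             gce = m$gce, bde = m$bde, psnr = m$psnr, mae = m$mae,
             energy_initial = case$energy_initial,
             energy_final = case$energy_final)
}

#' Run the full segmentation cascade on a phantom suite
#'
#' For each case: generate a seeded phantom, map its truth box into the
#' localization frame, jitter it with the surrogate localizer, map the
#' detection back to full resolution, segment inside the box, and score
#' the result against the exact ground truth. Per-case failures are
#' recorded and the run continues.
#'
#' @param config A [run_config()].
#' @return A `cascade_result`: list with `summary` (one data.frame row
#'   per case), `cases` (full per-case records), and `config`. When
#'   `config$outdir` is set, phantom images (16-bit TIFF), predicted and
#'   truth masks (0/255 PNG), `summary.csv` and `truth.json` are written
#'   there.
#' @export
run_cascade <- function(config = run_config()) {
  method <- match.arg(config$method, c("chanvese", "prewitt"))
  cases <- vector("list", config$n)
  rows <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    case_seed <- config$seed + i
    cases[[i]] <- tryCatch(
      run_one_case(config, case_seed, method),
      error = function(e) list(seed = case_seed, error = conditionMessage(e))
    )
    rows[[i]] <- if (is.null(cases[[i]]$error)) case_row(cases[[i]]) else NULL
  }
  summary <- do.call(rbind, rows)
  out <- structure(list(summary = summary, cases = cases, config = config),
                   class = "cascade_result")
  if (!is.null(config$outdir)) write_cascade(out, config$outdir)
  out
}

write_cascade <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth_list <- list()
  for (i in seq_along(result$cases)) {
    case <- result$cases[[i]]
    if (!is.null(case$error)) next
    tag <- sprintf("%04d", i)
    write_image(case$image, file.path(outdir, paste0("image_", tag, ".tiff")))
    write_mask(case$mask, file.path(outdir, paste0("mask_", tag, ".png")))
    write_mask(case$truth$mask,
               file.path(outdir, paste0("truth_", tag, ".png")))
    truth_list[[tag]] <- list(seed = case$seed, label = case$truth$label,
                              box = bbox_to_list(case$truth$box),
                              detected = bbox_to_list(case$box))
  }
  jsonlite::write_json(truth_list, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' Compare segmentation methods on a common phantom suite
#'
#' Runs the cascade once per method on identical seeds (so every case
#' pairs the same phantom, truth, and jittered box across arms) and
#' tabulates per-method means of all seven segmentation metrics, one row
#' per method.
#'
#' @param config A [run_config()]; its `method` field is ignored.
#' @param methods Methods to compare.
#' @return List with `table` (per-method mean metrics, a data.frame) and
#'   `runs` (named list of `cascade_result`s). With `config$outdir` set,
#'   the table is written as `comparison.csv`.
#' @export
compare_methods <- function(config = run_config(),
                            methods = c("chanvese", "prewitt")) {
  runs <- list()
  rows <- list()
  for (m in methods) {
    cfg <- config
    cfg$method <- m
    cfg$outdir <- NULL
    runs[[m]] <- run_cascade(cfg)
    s <- runs[[m]]$summary
    if (is.null(s) || nrow(s) == 0L) {
      rows[[m]] <- NULL
      next
    }
    rows[[m]] <- data.frame(
      method = m,
      dice = mean(s$dice), rand_index = mean(s$rand_index),
      voi = mean(s$voi), gce = mean(s$gce),
      bde = mean(s$bde, na.rm = TRUE),
      psnr = mean(s$psnr[is.finite(s$psnr)]),
      mae = mean(s$mae), n = nrow(s)
    )
  }
  table <- do.call(rbind, rows)
  if (is.null(table)) table <- data.frame() else rownames(table) <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(config$outdir, "comparison.csv"),
                     row.names = FALSE)
  }
  list(table = table, runs = runs)
}
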