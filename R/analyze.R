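#' Full morphometric analysis of one binary volume
#'
#' Computes all five parameters, in both variants where variants exist:
#' BV/TV by voxel counting and by mesh-enclosed volume, BS with and without
#' the artificial cut surfaces, Tb.Th and Tb.Sp under the requested edge
#' policy, and DA by the requested MIL method and convention. Every value
#' carries a `variant_label` naming the algorithm/policy that produced it.
#'
#' @param img Binary `voxel_image`.
#' @param th_edges Thickness edge policy, `"include"` or `"exclude"`.
#' @param da_method `"test_lines"` or `"surface"`.
#' @param da_convention DA convention, see [degree_of_anisotropy()].
#' @param da_directions,da_spacing,seed MIL sampling parameters.
#' @return A `morphometry_result` list: `bvtv`, `bvtv_mesh`, `bs`,
#'   `bs_excl_boundary`, `tb_th_mean`, `tb_th_sd`, `tb_sp_mean`, `tb_sp_sd`,
#'   `da`, and `variant_labels`. Parameters undefined for the input (e.g.
#'   Tb.Sp of a solid volume, DA without an interface) are `NA`.
#' @export
analyze_volume <- function(img, th_edges = c("include", "exclude"),
                           da_method = c("test_lines", "surface"),
                           da_convention = "eigen_ratio",
                           da_directions = 128, da_spacing = 1, seed = 0) {
  stopifnot_binary(img)
  th_edges <- match.arg(th_edges)
  da_method <- match.arg(da_method)
  policy <- if (th_edges == "include") "include_edges" else
    "exclude_edge_voxels"
  mesh <- triangulate(img, cap_boundary = TRUE)
  bvtv <- bvtv_voxel(img)
  bvtv_m <- if (nrow(mesh$triangles) > 0) bvtv_mesh(mesh, img) else 0
  bs_in <- bone_surface(mesh, include_boundary = TRUE)
  bs_ex <- bone_surface(mesh, include_boundary = FALSE)
  th <- tryCatch(tb_stats(local_thickness(img, "foreground", policy)),
                 error = function(e) c(mean = NA_real_, sd = NA_real_, n = 0))
  sp <- tryCatch(tb_stats(local_thickness(img, "background", policy)),
                 error = function(e) c(mean = NA_real_, sd = NA_real_, n = 0))
  da <- tryCatch({
    dist <- if (da_method == "test_lines")
      mil_test_lines(img, da_directions, da_spacing, seed)
    else
      mil_surface_projection(img, mesh, da_directions)
    degree_of_anisotropy(fit_mil_ellipsoid(dist), da_convention)
  }, error = function(e) NULL)
  structure(list(
    bvtv = bvtv, bvtv_mesh = bvtv_m, bs = bs_in, bs_excl_boundary = bs_ex,
    tb_th_mean = th[["mean"]], tb_th_sd = th[["sd"]],
    tb_sp_mean = sp[["mean"]], tb_sp_sd = sp[["sd"]],
    da = if (is.null(da)) NA_real_ else da$da,
    da_principal_axis = if (is.null(da)) NULL else da$principal_axis,
    variant_labels = c(
      bvtv = "voxel_count", bvtv_mesh = "mesh_enclosed",
      bs = "triangulated_include_boundary",
      bs_excl_boundary = "triangulated_exclude_boundary",
      tb_th = paste0("maximal_spheres_", policy),
      tb_sp = paste0("maximal_spheres_", policy),
      da = if (is.null(da)) "failed" else
        paste0("mil_", da_method, "_", da_convention))),
    class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result>\n")
  cat(sprintf("  BV/TV  %.4f (voxel)   %.4f (mesh)\n", x$bvtv, x$bvtv_mesh))
  cat(sprintf("  BS     %.4f mm^2 (incl. boundary)  %.4f mm^2 (excl.)\n",
              x$bs, x$bs_excl_boundary))
  cat(sprintf("  Tb.Th  %.4f +/- %.4f mm\n", x$tb_th_mean, x$tb_th_sd))
  cat(sprintf("  Tb.Sp  %.4f +/- %.4f mm\n", x$tb_sp_mean, x$tb_sp_sd))
  cat(sprintf("  DA     %.4f (%s)\n", x$da, x$variant_labels[["da"]]))
  invisible(x)
}

#' Long-format rows for one analysed sample
#'
#' @param result A `morphometry_result`.
#' @param sample Sample identifier.
#' @return Data frame with columns `sample`, `parameter`, `value`, `units`,
#'   `variant_label`.
#' @export
morphometry_rows <- function(result, sample = "sample") {
  vl <- result$variant_labels
  data.frame(
    sample = sample,
    parameter = c("BV/TV", "BV/TV", "BS", "BS", "Tb.Th", "Tb.Sp", "DA"),
    value = c(result$bvtv, result$bvtv_mesh, result$bs,
              result$bs_excl_boundary, result$tb_th_mean, result$tb_sp_mean,
              result$da),
    units = c("1", "1", "mm2", "mm2", "mm", "mm", "1"),
    variant_label = c(vl[["bvtv"]], vl[["bvtv_mesh"]], vl[["bs"]],
                      vl[["bs_excl_boundary"]], vl[["tb_th"]], vl[["tb_sp"]],
                      vl[["da"]]),
    stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Serializable settings for [run_analyze()]; a run re-executed from the
#' same configuration and seed is bit-identical for deterministic stages.
#'
#' @param threshold Segmentation threshold for grayscale inputs; `NULL`
#'   (default) expects binary inputs.
#' @param preprocess A [preprocess_config()] used when `threshold` is set.
#' @param th_edges,da_method,da_convention,da_directions,da_spacing,seed
#'   Variant switches, see [analyze_volume()].
#' @param voxel_size Spacing override for formats without metadata (TIFF).
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = NULL, preprocess = NULL,
                       th_edges = "include", da_method = "test_lines",
                       da_convention = "eigen_ratio", da_directions = 128,
                       da_spacing = 1, seed = 0, voxel_size = NULL) {
  if (!is.null(threshold) && is.null(preprocess))
    preprocess <- preprocess_config(threshold = threshold)
  structure(list(threshold = threshold, preprocess = preprocess,
                 th_edges = th_edges, da_method = da_method,
                 da_convention = da_convention,
                 da_directions = da_directions, da_spacing = da_spacing,
                 seed = seed, voxel_size = voxel_size),
            class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

#' Analyse a batch of volumes
#'
#' Reads each input (file path, `voxel_image` or `phantom`), segments it if
#' a threshold is configured, runs [analyze_volume()], and writes a
#' long-format `results.csv` (one row per sample/parameter/variant) with a
#' provenance header (package version, configuration hash, seed), plus a
#' per-sample JSON sidecar and a run log. Failing samples are logged and
#' skipped; the run completes for the others.
#'
#' @param inputs Character vector of file paths, or a (possibly named) list
#'   of `voxel_image` / `phantom` objects.
#' @param output_dir Directory for `results.csv`, JSON sidecars and the log.
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (the long data frame),
#'   `n_failed`, and the `csv` path.
#' @export
run_analyze <- function(inputs, output_dir, config = run_config()) {
  if (length(inputs) == 0) stop("empty input: nothing to analyse")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  if (is.character(inputs)) {
    names(inputs) <- tools::file_path_sans_ext(basename(inputs),
                                               compression = TRUE)
  } else if (is.null(names(inputs))) {
    names(inputs) <- sprintf("sample%03d", seq_along(inputs))
  }
  cfg <- config
  rows <- list()
  failed <- 0L
  for (i in seq_along(inputs)) {
    nm <- names(inputs)[i]
    res <- tryCatch({
      x <- inputs[[i]]
      img <- if (inherits(x, "phantom")) x$image
        else if (inherits(x, "voxel_image")) x
        else read_volume(x, voxel_size = cfg$voxel_size)
      if (!img$is_binary) {
        if (is.null(cfg$threshold))
          stop("grayscale input but no threshold configured")
        img <- segment(img, cfg$preprocess)
      }
      analyze_volume(img, th_edges = cfg$th_edges, da_method = cfg$da_method,
                     da_convention = cfg$da_convention,
                     da_directions = cfg$da_directions,
                     da_spacing = cfg$da_spacing, seed = cfg$seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      say("WARNING sample '%s' failed: %s", nm, conditionMessage(res))
      next
    }
    rows[[nm]] <- morphometry_rows(res, nm)
    jsonlite::write_json(
      res[setdiff(names(res), "da_principal_axis")],
      file.path(output_dir, paste0(nm, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
    say("sample '%s' done", nm)
  }
  results <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else stop("empty input: no sample could be analysed")
  csv <- file.path(output_dir, "results.csv")
  header <- c(
    sprintf("# trabemorph %s", as.character(utils::packageVersion("trabemorph"))),
    sprintf("# config_hash %s", config_hash(cfg)),
    sprintf("# seed %d", as.integer(cfg$seed)))
  con <- file(csv, "w")
  writeLines(header, con)
  write.csv(results, con, row.names = FALSE)
  close(con)
  writeLines(log_lines, log_path)
  say("wrote %s (%d samples, %d failed)", csv, length(rows), failed)
  invisible(list(results = results, n_failed = failed, csv = csv))
}

#' Read a results CSV written by [run_analyze()]
#'
#' @param path Path to `results.csv` (provenance header lines are skipped).
#' @return The long-format results data frame.
#' @export
read_results <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
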