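# End-to-end orchestration: simulate (or load) -> calibrate thresholds on
# the negative control -> colocalization -> detect and call cells ->
# segment regions and regionalise -> tissue-specific read-outs -> write a
# reproducible run directory with a content-hash manifest.

pipeline_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("failed at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline into a run directory
#'
#' The run configuration is a named list (or a YAML file path) with:
#' \describe{
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{seed recorded in the manifest and used for simulation.}
#'   \item{sim}{a [sim_config()] for a synthetic run; its matched
#'     negative control is generated automatically.  Alternatively give
#'     `image` and `control_image` TIFF paths.}
#'   \item{tet_channel, costain_channel, cd4_channel}{channel roles
#'     (defaults `CD1dTet`, `CD3`, `CD4`; `cd4_channel` optional).}
#'   \item{q}{control quantile for thresholds (default 0.999).}
#'   \item{min_area, max_area}{detection size window, um2.}
#'   \item{smoothing_scale}{region-segmentation scale, um.}
#'   \item{band_width}{CMJ band width, um (thymus).}
#'   \item{void_min_area}{void size cutoff, um2 (thymus).}
#'   \item{gates}{optional [gate_tree()] (or JSON path) to run
#'     histo-cytometry.}
#' }
#' Outputs: `cells.csv`, `region_map.tif(+.json)`, `region_stats.csv`,
#' `thresholds.json`, `coloc.json`, `counts.json`, `cmj_band.json` and
#' `voids.json` (thymus), `features.csv`/`gate_stats.csv` (when gating),
#' and `manifest.json` with the config, seed and md5 content hashes of
#' every output.  Identical config + seed give identical hashes.
#'
#' @param config Named list or YAML path as described.
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop_validation("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  tet <- config$tet_channel %||% "CD1dTet"
  costain <- config$costain_channel %||% "CD3"
  cd4 <- config$cd4_channel %||% "CD4"
  q <- config$q %||% 0.999

  inputs <- pipeline_stage("input", out_dir, {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      cfg$seed <- as.integer(seed)
      wt <- generate_section(cfg)
      ctrl <- generate_negative_control(cfg)
      list(image = wt$image, control = ctrl$image, tissue = cfg$tissue)
    } else {
      img <- read_image(config$image)
      ctl <- read_image(config$control_image)
      list(image = img, control = ctl,
           tissue = config$tissue %||% "spleen")
    }
  })
  image <- max_project(inputs$image)
  control <- max_project(inputs$control)

  thresholds <- pipeline_stage("thresholds", out_dir, {
    chans <- intersect(c(tet, costain, cd4), names(image$channels))
    th <- calibrate_thresholds(control, chans, q = q,
                               control_id = "negative_control")
    write_thresholds(th, file.path(out_dir, "thresholds.json"))
    th
  })

  coloc <- pipeline_stage("colocalization", out_dir, {
    res <- list(
      pearson_wt = as.numeric(pearson_coloc(image, tet, costain)),
      pearson_control = as.numeric(pearson_coloc(control, tet, costain)),
      costain_wt = costain_area(image, tet, costain, thresholds),
      costain_control = costain_area(control, tet, costain, thresholds))
    jsonlite::write_json(res, file.path(out_dir, "coloc.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  cells <- pipeline_stage("detection", out_dir, {
    obj <- detect_tetramer_objects(image, tet, thresholds,
                                   min_area = config$min_area %||% 10,
                                   max_area = config$max_area %||% 200)
    obj <- call_specific_cells(obj, costain, thresholds)
    if (cd4 %in% names(image$channels))
      obj <- classify_cd4_subset(obj, cd4, thresholds)
    obj
  })

  regions <- pipeline_stage("regions", out_dir, {
    rm <- segment_regions(image, inputs$tissue,
                          smoothing_scale = config$smoothing_scale %||% 10)
    write_region_map(rm, file.path(out_dir, "region_map.tif"))
    rm
  })

  cells <- assign_cells(cells, regions, image$meta)
  stats <- pipeline_stage("region_stats", out_dir, {
    st <- region_stats(cells, regions, image$meta)
    utils::write.csv(st, file.path(out_dir, "region_stats.csv"),
                     row.names = FALSE)
    st
  })

  extras <- list()
  if (inputs$tissue == "thymus") {
    bc <- pipeline_stage("cmj_band", out_dir, {
      cmj_band_count(cells, regions, image$meta,
                     band_width = config$band_width %||% 100)
    })
    cells <- bc$cells
    extras$band <- bc[setdiff(names(bc), "cells")]
    jsonlite::write_json(extras$band, file.path(out_dir, "cmj_band.json"),
                         auto_unbox = TRUE, digits = NA)
    extras$voids <- pipeline_stage("voids", out_dir, {
      med <- regions$labels == match("medulla", regions$vocab)
      vr <- detect_voids(image, med, k5_channel = config$k5_channel %||% "K5",
                         min_area = config$void_min_area %||% 5000)
      jsonlite::write_json(unclass(vr), file.path(out_dir, "voids.json"),
                           auto_unbox = TRUE, digits = NA)
      vr
    })
  }

  if (!is.null(config$gates)) {
    extras$histo <- pipeline_stage("histocytometry", out_dir, {
      tree <- if (is.character(config$gates)) read_gate_tree(config$gates)
              else config$gates
      labels <- segment_nuclei(image)
      feats <- extract_features(labels, image)
      gated <- apply_gates(feats, tree)
      write_cell_table(gated, file.path(out_dir, "features.csv"))
      utils::write.csv(attr(gated, "gate_stats"),
                       file.path(out_dir, "gate_stats.csv"),
                       row.names = FALSE)
      attr(gated, "gate_stats")
    })
  }

  pipeline_stage("export", out_dir, {
    write_cell_table(cells, file.path(out_dir, "cells.csv"))
    counts <- list(
      n_objects = nrow(cells),
      n_specific = sum(cells$costain_positive, na.rm = TRUE),
      count_per_0.63mm2 = count_per_field(cells, image$meta))
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- sort(setdiff(list.files(out_dir), c("manifest.json", "FAILED")))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(seed = seed,
                   config = config[setdiff(names(config), "sim")],
                   sim = if (!is.null(config$sim)) unclass(config$sim),
                   hashes = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  structure(invisible(out_dir), manifest = manifest)
}

#' Aggregate runs into per-group summaries (mean +/- SEM)
#'
#' Treats each run directory as one image, averages per-region counts and
#' densities within each mouse, then reports group means and standard
#' errors of the per-mouse values.  No hypothesis tests are performed;
#' the table is ready for external statistics software.
#'
#' @param grouping data.frame with columns `dir` (run directory), `mouse`
#'   and `group`.
#' @return data.frame with one row per group x region: `n_mice`,
#'   `mean_count`, `sem_count`, `mean_density`, `sem_density` (SEM is
#'   `NA` for a single mouse).
#' @export
summarize_mice <- function(grouping) {
  if (!nrow(grouping)) stop_validation("empty grouping table")
  per_image <- do.call(rbind, lapply(seq_len(nrow(grouping)), function(i) {
    st <- utils::read.csv(file.path(grouping$dir[i], "region_stats.csv"),
                          stringsAsFactors = FALSE)
    st <- st[st$region != "unassigned", ]
    st$mouse <- grouping$mouse[i]
    st$group <- grouping$group[i]
    st
  }))
  sem <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(per_image,
                                     list(per_image$group, per_image$region),
                                     drop = TRUE), function(d) {
    per_mouse_count <- tapply(d$count, d$mouse, mean)
    per_mouse_dens <- tapply(d$density_per_mm2, d$mouse, mean)
    data.frame(group = d$group[1], region = d$region[1],
               n_mice = length(per_mouse_count),
               mean_count = mean(per_mouse_count),
               sem_count = sem(as.numeric(per_mouse_count)),
               mean_density = mean(per_mouse_dens),
               sem_density = sem(as.numeric(per_mouse_dens)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$region), ]
}
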