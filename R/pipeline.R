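#' Run the full connectome analysis pipeline
#'
#' Orchestrates the whole analysis from a configuration: optional image
#' quantification (slice image + label map -> per-region counts), then
#' connectome construction, dyad classification, degree/strength tables,
#' hub analysis, module detection on projection profiles, within-module
#' degree Z-scores and participation coefficients, cartographic roles,
#' the ipsi-vs-contra and afferent-vs-efferent t-tests, and all exports
#' (CSV tables, GraphML, GEXF), plus a plain-text run log recording
#' package version, configuration hash and seed. Outputs are a pure
#' function of (inputs, configuration, seed); a failure in any stage
#' removes the partially written bundle and aborts with the stage name.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{counts}{Count table data.frame, or path to a counts CSV.
#'       Alternative to `image`.}
#'     \item{image}{Optional list `signal, labels, regions` of file paths
#'       (slice TIFF, label TIFF, region CSV) plus optional
#'       `threshold_value`, `min_area_px`, `max_area_px`; when present the
#'       imaging stage produces the count table (every region's injection
#'       attribution must then be supplied via `image$injection`).}
#'     \item{node_set}{Region names (default [vsb_regions()]).}
#'     \item{cut}{`list(k = ...)` or `list(h = ...)` module cut rule
#'       (default `list(k = 3)`).}
#'     \item{linkage}{Clustering linkage (default `"complete"`).}
#'     \item{w_max}{Display-weight ceiling (default 0.9).}
#'     \item{alpha}{Significance level (default 0.05).}
#'     \item{seed}{Integer seed recorded in the log (default 1).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `counts`, `graph`,
#'   `dyads`, `degrees`, `strengths`, `partition`, `roles`, `stats`,
#'   `files`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop_input("reading a JSON config requires the 'jsonlite' package")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  node_set <- config$node_set %||% vsb_regions()
  cut <- config$cut %||% list(k = 3)
  linkage <- config$linkage %||% "complete"
  w_max <- config$w_max %||% 0.9
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1L

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  counts <- stage("input", {
    if (!is.null(config$image)) {
      quantify_image_config(config$image, node_set)
    } else if (is.character(config$counts)) {
      read_counts(config$counts)
    } else if (is.data.frame(config$counts)) {
      validate_counts(config$counts)
    } else {
      stop("config needs 'counts' (table or CSV path) or 'image'")
    }
  })
  emit("counts.csv", function(p) write_counts(counts, p))

  g <- stage("connectome", build_connectome(counts, node_set))
  dyads <- stage("dyads", classify_dyads(g))
  emit("dyads.csv", function(p) {
    utils::write.csv(as.data.frame(dyads), p, row.names = FALSE)
  })

  degrees <- stage("degree", node_degree_unweighted(g))
  strengths <- stage("strength", node_strength(g))
  emit("degrees.csv", function(p) utils::write.csv(degrees, p,
                                                   row.names = FALSE))
  emit("strengths.csv", function(p) utils::write.csv(strengths, p,
                                                     row.names = FALSE))

  partition <- stage("modules", {
    prof <- projection_profile(counts, node_set)
    detect_modules(prof, h = cut$h, k = cut$k, linkage = linkage)
  })
  emit("dendrogram_merges.csv", function(p) {
    m <- partition$tree$merge
    utils::write.csv(data.frame(left = m[, 1], right = m[, 2],
                                height = partition$tree$height), p,
                     row.names = FALSE)
  })

  roles <- stage("roles", node_roles(g, partition))
  emit("roles.csv", function(p) utils::write.csv(roles, p,
                                                 row.names = FALSE))

  stats_tab <- stage("stats", {
    aff <- node_strength(g)$afferent
    eff <- node_strength(g)$efferent
    rbind(
      cbind(comparison = "ipsi_vs_contra",
            ipsi_contra_test(counts, alpha = alpha)),
      cbind(comparison = "afferent_vs_efferent",
            unpaired_t(aff, eff, alpha = alpha))
    )
  })
  emit("stats.csv", function(p) utils::write.csv(stats_tab, p,
                                                 row.names = FALSE))

  stage("export", {
    gg <- annotate_connectome(g, roles)
    if (igraph::ecount(gg) > 0) gg <- scale_edge_weights(gg, w_max)
    emit("network.graphml", function(p) write_graphml(gg, p))
    emit("network.gexf", function(p) write_gexf(gg, p))
    emit("edges.csv", function(p) write_edge_list(gg, p))
    emit("adjacency.csv", function(p) write_adjacency(gg, p))
  })

  emit("run_log.txt", function(p) {
    cfg_file <- tempfile()
    on.exit(unlink(cfg_file))
    dput(config[order(names(config))], file = cfg_file)
    writeLines(c(
      sprintf("voleconnectome %s",
              as.character(utils::packageVersion("voleconnectome"))),
      sprintf("R %s", as.character(getRversion())),
      sprintf("config_md5 %s", unname(tools::md5sum(cfg_file))),
      sprintf("seed %d", as.integer(seed)),
      sprintf("nodes %d edges %d", igraph::vcount(g), igraph::ecount(g))
    ), p)
  })

  invisible(list(counts = counts, graph = g, dyads = dyads,
                 degrees = degrees, strengths = strengths,
                 partition = partition, roles = roles, stats = stats_tab,
                 files = written))
}

# Imaging stage of the pipeline: segment + count one slice and convert the
# per-region counts into a long-format count table for the configured
# injection region.
quantify_image_config <- function(image_cfg, node_set) {
  needed <- c("signal", "labels", "regions", "injection")
  if (!all(needed %in% names(image_cfg))) {
    stop("image config needs: ", paste(needed, collapse = ", "))
  }
  signal <- read_slice_image(image_cfg$signal)
  lm <- read_label_map(image_cfg$labels, image_cfg$regions)
  params <- if (!is.null(image_cfg$threshold_value)) {
    segmentation_params("fixed",
                        threshold_value = image_cfg$threshold_value,
                        min_area_px = image_cfg$min_area_px %||% 1,
                        max_area_px = image_cfg$max_area_px %||% Inf)
  } else {
    segmentation_params("automatic",
                        min_area_px = image_cfg$min_area_px %||% 1,
                        max_area_px = image_cfg$max_area_px %||% Inf)
  }
  seg <- segment_cells(signal, params)
  res <- count_per_region(seg, lm, params, signal)
  tab <- res$counts
  tab <- tab[tab$name != image_cfg$injection, , drop = FALSE]
  validate_counts(data.frame(
    injection = image_cfg$injection,
    source = tab$name,
    side = tab$hemisphere,
    count = tab$cell_count,
    stringsAsFactors = FALSE
  ))
}
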