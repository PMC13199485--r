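#' Read protein sequences from FASTA
#'
#' Thin wrapper returning a named character vector of uppercase sequences.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta_aa <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(unlist(seqs)), names(seqs))
}


validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_field("config", "must be a list or YAML path")
  if (is.null(config$out_dir)) stop_field("out_dir", "is required")
  # every referenced input path must exist before any stage runs
  paths <- c(config$screen$explants, config$screen$embryo,
             config$shape$series, config$kinetics$tracks,
             config$quant$ddct$path, config$quant$gag$path,
             config$quant$align$path)
  for (p in paths)
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config: input path `%s` does not exist", p),
           call. = FALSE)
  config
}

#' Run the convergence-and-extension analysis pipeline
#'
#' Executes the configured stages in order (simulate -> screen -> shape ->
#' kinetics -> quant), writing tidy per-stage outputs and a run manifest
#' (config snapshot, input checksums, package version, per-stage row
#' counts, warnings) to the output directory. When a `simulate` block is
#' present its outputs become the default inputs of downstream stages.
#' Identical config and inputs reproduce identical outputs.
#'
#' @param config Named list or path of a YAML file. Blocks: `out_dir`,
#'   `seed`, and any of `simulate` (sub-blocks `expression`, `tracks`,
#'   `shapes` with generator spec fields), `screen` (`explants`: TSV
#'   paths, `embryo`: TSV path, `criteria`: [screen_criteria()] fields),
#'   `shape` (`series`: CSV path, inclusion cutoffs), `kinetics`
#'   (`tracks`: CSV path, `midline_x`, `scale`, filter options), `quant`
#'   (`ddct`, `gag`, `align` sub-blocks).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- list(package_version =
                     as.character(utils::packageVersion("cetime")),
                   config = config, stages = list(), warnings = list())
  inputs <- list()
  record <- function(stage, info) manifest$stages[[stage]] <<- info
  wrap <- function(stage, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      manifest$warnings[[length(manifest$warnings) + 1]] <<-
        sprintf("%s: %s", stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      manifest$status <<- sprintf("failed at stage %s", stage)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, null = "null", digits = NA,
                           force = TRUE)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) wrap("simulate", {
    sim <- config$simulate
    counts <- list()
    if (!is.null(sim$expression)) {
      args <- sim$expression
      args$planted_triggers <- unlist(args$planted_triggers)
      args$seed <- args$seed %||% seed
      spec <- do.call(sim_expression_spec, args)
      panel <- gen_expression_panel(spec)
      # one TSV per explant condition plus an embryo confirmation series
      expl_paths <- character(0)
      for (cond in attr(panel, "conditions")) {
        p <- file.path(out_dir, sprintf("sim_expression_%s.tsv", cond))
        write_expression_tsv(panel[panel$condition == cond, ], p)
        expl_paths <- c(expl_paths, p)
      }
      espec <- spec
      espec$conditions <- "embryo"
      espec$seed <- substream_seed(spec$seed, 999983L)
      embryo <- gen_expression_panel(espec)
      epath <- file.path(out_dir, "sim_expression_embryo.tsv")
      write_expression_tsv(embryo, epath)
      inputs$screen_explants <- expl_paths
      inputs$screen_embryo <- epath
      counts$expression_rows <- nrow(panel)
    }
    if (!is.null(sim$tracks)) {
      args <- sim$tracks
      args$seed <- args$seed %||% seed
      tab <- gen_tracks(do.call(sim_track_spec, args))
      tpath <- file.path(out_dir, "sim_tracks.csv")
      write_tracks_csv(tab, tpath)
      inputs$kinetics_tracks <- tpath
      inputs$kinetics_midline <- attr(tab, "midline_x")
      inputs$kinetics_interval <- attr(tab, "frame_interval")
      counts$track_rows <- nrow(tab)
    }
    if (!is.null(sim$shapes)) {
      args <- sim$shapes
      args$seed <- args$seed %||% seed
      ser <- gen_shape_series(do.call(sim_shape_spec, args))
      spath <- file.path(out_dir, "sim_shapes.csv")
      write_shape_series_csv(ser, spath)
      inputs$shape_series <- spath
      counts$shape_rows <- sum(vapply(ser, nrow, 0L))
    }
    record("simulate", counts)
  })

  if (!is.null(config$screen)) wrap("screen", {
    sc <- config$screen
    expl_paths <- sc$explants %||% inputs$screen_explants
    epath <- sc$embryo %||% inputs$screen_embryo
    if (is.null(expl_paths) || is.null(epath))
      stop("screen stage needs explant and embryo inputs")
    crit <- do.call(screen_criteria, as.list(sc$criteria))
    explants <- lapply(unlist(expl_paths), read_expression_tsv)
    embryo <- read_expression_tsv(epath)
    cs <- run_screen(explants, embryo, crit)
    utils::write.csv(cs$audit, file.path(out_dir, "screen_audit.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(counts = as.list(cs$counts),
                              tier3 = cs$tier3),
                         file.path(out_dir, "screen_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    record("screen", list(genes_in = nrow(cs$audit),
                          counts = as.list(cs$counts)))
  })

  if (!is.null(config$shape)) wrap("shape", {
    sh <- config$shape
    spath <- sh$series %||% inputs$shape_series
    if (is.null(spath)) stop("shape stage needs a series input")
    series <- read_shape_series_csv(spath)
    incl <- vapply(series, function(s)
      isTRUE(include_explant(s, sh$cutoff_roundness %||% 0.5,
                             sh$cutoff_time_hpf %||% 12)$include),
      logical(1))
    kept <- series[incl]
    rows <- lapply(names(kept), function(id) {
      fit <- fit_boltzmann(kept[[id]])
      onset <- extension_onset_from_series(kept[[id]])
      cbind(data.frame(explant_id = id),
            as.data.frame(as.list(fit$coefficients)),
            data.frame(sse = fit$sse, onset_hpf = onset))
    })
    fits <- do.call(rbind, rows)
    utils::write.csv(fits, file.path(out_dir, "shape_fits.csv"),
                     row.names = FALSE)
    record("shape", list(series_in = length(series),
                         included = length(kept)))
  })

  if (!is.null(config$kinetics)) wrap("kinetics", {
    kn <- config$kinetics
    tpath <- kn$tracks %||% inputs$kinetics_tracks
    if (is.null(tpath)) stop("kinetics stage needs a tracks input")
    tab <- read_tracks_csv(tpath,
                           frame_interval = kn$frame_interval %||%
                             inputs$kinetics_interval %||% 5,
                           midline_x = kn$midline_x %||%
                             inputs$kinetics_midline %||% 0,
                           t0_hpf = kn$t0_hpf %||% 0,
                           scale = kn$scale %||% 1)
    ks <- kinetics_summary(tab, window = kn$window %||% 4,
                           min_frames = kn$min_frames %||% 3,
                           exclusion_radius_um =
                             kn$exclusion_radius_um %||% 100)
    utils::write.csv(ks$curve, file.path(out_dir, "kinetics_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(ks$per_track,
                     file.path(out_dir, "kinetics_tracks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(ks$onset),
                         file.path(out_dir, "kinetics_onset.json"),
                         auto_unbox = TRUE, digits = NA)
    record("kinetics", list(tracks = ks$n_tracks,
                            onset_hpf = ks$onset$onset_hpf))
  })

  if (!is.null(config$quant)) wrap("quant", {
    qu <- config$quant
    info <- list()
    if (!is.null(qu$ddct)) {
      tab <- utils::read.csv(qu$ddct$path, stringsAsFactors = FALSE)
      res <- ddct(tab, qu$ddct$target, qu$ddct$reference,
                  qu$ddct$calibrator)
      utils::write.csv(res, file.path(out_dir, "quant_ddct.csv"),
                       row.names = FALSE)
      info$ddct_samples <- nrow(res)
    }
    if (!is.null(qu$gag)) {
      tab <- utils::read.csv(qu$gag$path, stringsAsFactors = FALSE)
      res <- quantify_disaccharides(tab,
                                    qu$gag$standard_pmol %||% 20,
                                    qu$gag$protein_ug)
      utils::write.csv(res, file.path(out_dir, "quant_gag.csv"),
                       row.names = FALSE)
      info$gag_codes <- nrow(res)
    }
    if (!is.null(qu$align)) {
      seqs <- read_fasta_aa(qu$align$path)
      if (length(seqs) < 2) stop("align needs >= 2 sequences in FASTA")
      st <- pairwise_identity_similarity(seqs[[1]], seqs[[2]])
      jsonlite::write_json(unclass(st)[c("identity", "similarity",
                                         "alignment_length",
                                         "gap_count", "score")],
                           file.path(out_dir, "quant_align.json"),
                           auto_unbox = TRUE, digits = NA)
      info$align_identity <- st$identity
    }
    record("quant", info)
  })

  # input checksums for reproducibility bookkeeping
  in_paths <- unique(unlist(c(config$screen$explants,
                              config$screen$embryo, config$shape$series,
                              config$kinetics$tracks, inputs$screen_explants,
                              inputs$screen_embryo, inputs$shape_series,
                              inputs$kinetics_tracks)))
  in_paths <- in_paths[vapply(in_paths, is.character, TRUE)]
  if (length(in_paths))
    manifest$input_md5 <- as.list(tools::md5sum(in_paths))
  manifest$status <- manifest$status %||% "ok"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  invisible(manifest)
}
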