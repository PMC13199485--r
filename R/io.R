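# File-format readers and writers. Every reader validates rather than
# silently coercing; rejection messages name the offending row or column.

#' Write an expression panel as TSV (+ stage sidecar)
#'
#' First column `gene`; remaining columns named `<stage>|<condition>|<rep>`.
#' The stage label -> hpf map is written to a YAML sidecar
#' `<path>.stages.yaml`.
#'
#' @param panel An [expression_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(panel, path) {
  sh <- attr(panel, "stage_hpf")
  key <- sprintf("%s|%s|%s", panel$stage, panel$condition, panel$replicate)
  genes <- unique(panel$gene)
  cols <- unique(key[order(match(panel$stage, names(sh)), panel$condition,
                           panel$replicate)])
  wide <- matrix(NA_real_, length(genes), length(cols),
                 dimnames = list(genes, cols))
  wide[cbind(match(panel$gene, genes), match(key, cols))] <- panel$tpm
  df <- data.frame(gene = genes, wide, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(as.list(sh), paste0(path, ".stages.yaml"))
  invisible(path)
}

#' Read an expression panel from TSV
#'
#' @param path TSV path written in the `<stage>|<condition>|<rep>` schema.
#' @param stages_yaml Path of the stage -> hpf YAML sidecar (default
#'   `<path>.stages.yaml`).
#' @return An [expression_panel()].
#' @export
read_expression_tsv <- function(path, stages_yaml = NULL) {
  stages_yaml <- stages_yaml %||% paste0(path, ".stages.yaml")
  if (!file.exists(stages_yaml))
    stop(sprintf("stage sidecar `%s` not found", stages_yaml),
         call. = FALSE)
  sh <- unlist(yaml::read_yaml(stages_yaml))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no data rows", call. = FALSE)
  if (names(df)[1] != "gene")
    stop("first column must be `gene`", call. = FALSE)
  dup <- duplicated(df$gene)
  if (any(dup))
    stop(sprintf("duplicated gene id `%s`", df$gene[dup][1]),
         call. = FALSE)
  cols <- names(df)[-1]
  parts <- strsplit(cols, "|", fixed = TRUE)
  bad <- cols[lengths(parts) != 3]
  if (length(bad))
    stop(sprintf("malformed header column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  meta <- do.call(rbind, parts)
  badstage <- setdiff(unique(meta[, 1]), names(sh))
  if (length(badstage))
    stop(sprintf("stage(s) missing from sidecar: %s",
                 paste(badstage, collapse = ", ")), call. = FALSE)
  long <- data.frame(
    gene = rep(df$gene, times = length(cols)),
    stage = rep(meta[, 1], each = nrow(df)),
    condition = rep(meta[, 2], each = nrow(df)),
    replicate = rep(as.integer(meta[, 3]), each = nrow(df)),
    tpm = unlist(df[-1], use.names = FALSE))
  neg <- which(!is.na(long$tpm) & long$tpm < 0)
  if (length(neg)) {
    r <- neg[1]
    stop(sprintf("negative TPM for gene `%s` in column `%s|%s|%s`",
                 long$gene[r], long$stage[r], long$condition[r],
                 long$replicate[r]), call. = FALSE)
  }
  long <- long[!is.na(long$tpm), , drop = FALSE]
  long$hpf <- unname(sh[long$stage])
  sh_sorted <- sort(sh)
  expression_panel(long[, c("gene", "stage", "hpf", "condition",
                            "replicate", "tpm")], stage_hpf = sh_sorted)
}

#' Write a track table as CSV
#'
#' @param table A [track_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

default_track_column_maps <- list(
  generic = c(track_id = "track_id", frame = "frame", x = "x", y = "y",
              t_hpf = "t_hpf"),
  trackmate = c(track_id = "TRACK_ID", frame = "FRAME", x = "POSITION_X",
                y = "POSITION_Y", t_hpf = "POSITION_T"))

#' Read a track table from CSV
#'
#' Accepts either generic `track_id`/`frame`/`x`/`y`(`/t_hpf`) columns or
#' the common tracker-export convention
#' `TRACK_ID`/`FRAME`/`POSITION_X`/`POSITION_Y`(`/POSITION_T`) without a
#' custom map.
#'
#' @param path CSV path.
#' @param column_map Named character vector mapping canonical names
#'   (`track_id`, `frame`, `x`, `y`, optionally `t_hpf`) to file columns.
#' @param frame_interval Minutes per frame.
#' @param midline_x Midline x, um (applied after scaling).
#' @param t0_hpf Time of frame 0 when no time column is present.
#' @param scale Isotropic pixel-to-um scale factor applied to x and y.
#' @return A [track_table()].
#' @export
read_tracks_csv <- function(path, column_map = NULL, frame_interval = 5,
                            midline_x = 0, t0_hpf = 0, scale = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(column_map)) {
    for (cm in default_track_column_maps)
      if (all(cm[c("track_id", "frame", "x", "y")] %in% names(df))) {
        column_map <- cm
        break
      }
    if (is.null(column_map))
      stop("cannot infer track columns; supply `column_map`",
           call. = FALSE)
  }
  need <- c("track_id", "frame", "x", "y")
  miss <- need[!column_map[need] %in% names(df)]
  if (length(miss))
    stop(sprintf("mapped column(s) missing from file: %s",
                 paste(column_map[miss], collapse = ", ")), call. = FALSE)
  out <- data.frame(track_id = df[[column_map[["track_id"]]]],
                    frame = df[[column_map[["frame"]]]],
                    x = df[[column_map[["x"]]]] * scale,
                    y = df[[column_map[["y"]]]] * scale)
  for (col in c("frame", "x", "y"))
    if (!is.numeric(out[[col]]))
      stop(sprintf("column `%s` is not numeric", column_map[[col]]),
           call. = FALSE)
  if ("t_hpf" %in% names(column_map) &&
      column_map[["t_hpf"]] %in% names(df))
    out$t_hpf <- df[[column_map[["t_hpf"]]]]
  track_table(out, frame_interval = frame_interval,
              midline_x = midline_x, t0_hpf = t0_hpf)
}

#' Write / read shape series CSV
#'
#' Tidy format: one row per frame with columns `explant_id`, `group`,
#' `hpf`, `roundness`.
#'
#' @param series A `shape_series` or list of them.
#' @param path CSV path.
#' @return `path` (write) or a list of `shape_series` (read).
#' @export
write_shape_series_csv <- function(series, path) {
  if (is.data.frame(series)) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shape_series_csv
#' @export
read_shape_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("explant_id", "group", "hpf", "roundness")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  lapply(split(df, df$explant_id), function(d)
    shape_series(d$explant_id[1], d$group[1], d$hpf, d$roundness))
}

#' Write / read multi-frame label masks as TIFF
#'
#' Label values are stored as 16-bit samples; round-trips exactly for
#' labels below 65536.
#'
#' @param masks List of integer matrices.
#' @param path TIFF path.
#' @return `path` (write) or a list of integer matrices (read).
#' @export
write_mask_tiff <- function(masks, path) {
  if (is.matrix(masks)) masks <- list(masks)
  imgs <- lapply(masks, function(m) {
    if (any(m < 0 | m > 65535))
      stop("labels must lie in 0..65535 for 16-bit TIFF", call. = FALSE)
    m / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) {
    storage <- round(m * 65535)
    mode(storage) <- "integer"
    storage
  })
}

#' Write / read boundary polygons CSV
#'
#' One row per vertex: `explant_id`, `frame`, `vertex`, `x`, `y`.
#'
#' @param polys Named list (by explant) of lists (by frame) of two-column
#'   vertex matrices.
#' @param path CSV path.
#' @return `path` (write) or the nested list (read).
#' @export
write_polygons_csv <- function(polys, path) {
  rows <- list()
  for (ex in names(polys)) for (fr in seq_along(polys[[ex]])) {
    v <- polys[[ex]][[fr]]
    rows[[length(rows) + 1]] <- data.frame(explant_id = ex, frame = fr,
                                           vertex = seq_len(nrow(v)),
                                           x = v[, 1], y = v[, 2])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygons_csv
#' @export
read_polygons_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("explant_id", "frame", "vertex", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  lapply(split(df, df$explant_id), function(d)
    lapply(split(d, d$frame), function(f)
      as.matrix(f[order(f$vertex), c("x", "y")])))
}
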