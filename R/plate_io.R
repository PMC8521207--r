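#' @keywords internal
"_PACKAGE"

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

READ_TYPES <- c("supernatant_fi", "lysate_fi", "t0_fi",
                "absorbance_570", "absorbance_600")

WELL_ROLES <- c("sample", "t0_control", "passive", "unstained_background",
                "no_cell_blank", "correction_control", "monitoring_control",
                "empty")

#' Construct a validated 8 x 12 plate grid
#'
#' A plate grid holds the raw readings of one 96-well plate for a single
#' read type (one fluorescence channel at one gain, or one absorbance
#' wavelength). Values are non-negative reals; `NA` marks wells the reader
#' did not report.
#'
#' @param plate_id Plate identifier.
#' @param read_type One of `"supernatant_fi"`, `"lysate_fi"`, `"t0_fi"`,
#'   `"absorbance_570"`, `"absorbance_600"`.
#' @param values 8 x 12 numeric matrix (rows A-H, columns 1-12). A plain
#'   matrix is accepted; dimnames are set to the standard well coordinates.
#' @param gain_tag Free-text gain/settings tag from the reader. Supernatant
#'   and lysate reads of one plate are expected to share a gain; a mismatch
#'   is reported downstream as a warning, not an error.
#' @return An object of class `cec_plate_grid`.
#' @export
plate_grid <- function(plate_id, read_type, values, gain_tag = "") {
  if (!is.character(plate_id) || length(plate_id) != 1 || !nzchar(plate_id))
    stopf("plate_id must be a non-empty string")
  read_type <- match.arg(read_type, READ_TYPES)
  values <- as.matrix(values)
  if (!all(dim(values) == c(8, 12)))
    stopf("plate grid must be 8 x 12 (rows A-H, columns 1-12), got %d x %d",
          nrow(values), ncol(values))
  storage.mode(values) <- "double"
  bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("negative reading at well %s%d in plate '%s' (%s)",
          PLATE_ROWS[bad[1, 1]], bad[1, 2], plate_id, read_type)
  dimnames(values) <- list(PLATE_ROWS, as.character(PLATE_COLS))
  structure(list(plate_id = plate_id, read_type = read_type,
                 gain_tag = as.character(gain_tag), values = values),
            class = "cec_plate_grid")
}

#' @export
print.cec_plate_grid <- function(x, ...) {
  cat(sprintf("<cec_plate_grid> plate %s, %s (gain '%s'), %d wells read\n",
              x$plate_id, x$read_type, x$gain_tag, sum(!is.na(x$values))))
  invisible(x)
}

#' Read a plate grid CSV
#'
#' The dialect is a plain-text export: line 1 is the header
#' `plate_id,read_type,gain_tag`, line 2 its values, line 3 the column
#' header `well,1,...,12`, then eight rows labelled A-H with twelve
#' readings each. Empty cells are missing wells (never zero).
#'
#' @param path File path.
#' @param read_type Optional expected read type; a mismatch with the file
#'   header is an error.
#' @return A [plate_grid()] object.
#' @export
read_plate_grid <- function(path, read_type = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 11)
    stopf("%s: expected 11 lines (2 header + column row + 8 plate rows), got %d",
          path, length(lines))
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr[1:3]), c("plate_id", "read_type", "gain_tag")))
    stopf("%s: line 1 must be 'plate_id,read_type,gain_tag'", path)
  meta <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(meta) < 2) stopf("%s: line 2 must carry plate_id and read_type", path)
  file_type <- trimws(meta[2])
  if (!file_type %in% READ_TYPES)
    stopf("%s: unknown read_type '%s'", path, file_type)
  if (!is.null(read_type) && !identical(read_type, file_type))
    stopf("%s: file is a %s grid, %s requested", path, file_type, read_type)
  vals <- matrix(NA_real_, 8, 12)
  for (i in seq_len(8)) {
    cells <- strsplit(lines[3 + i], ",", fixed = TRUE)[[1]]
    # a trailing run of empty cells is dropped by strsplit; pad
    length(cells) <- 13
    lab <- trimws(cells[1])
    if (!identical(lab, PLATE_ROWS[i]))
      stopf("%s: row %d labelled '%s', expected '%s'", path, i, lab, PLATE_ROWS[i])
    for (j in seq_len(12)) {
      cell <- trimws(cells[j + 1])
      if (is.na(cell) || !nzchar(cell)) next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v))
        stopf("%s: non-numeric value '%s' at well %s%d", path, cell, lab, j)
      if (v < 0)
        stopf("%s: negative value at well %s%d", path, lab, j)
      vals[i, j] <- v
    }
  }
  plate_grid(trimws(meta[1]), file_type, vals,
             gain_tag = if (length(meta) >= 3) trimws(meta[3]) else "")
}

#' Write a plate grid CSV
#'
#' Values are rendered with `%.17g`, enough digits that reading the file
#' back reproduces every double bit-exactly; missing wells are empty cells.
#'
#' @param grid A [plate_grid()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cec_plate_grid"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  rows <- vapply(seq_len(8), function(i) {
    paste(c(PLATE_ROWS[i], fmt(grid$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c("plate_id,read_type,gain_tag",
               paste(grid$plate_id, grid$read_type, grid$gain_tag, sep = ","),
               paste(c("well", PLATE_COLS), collapse = ","),
               rows), path)
  invisible(path)
}

#' Construct and validate a plate layout
#'
#' A layout assigns each used well of one plate a role and, for sample-like
#' roles, a sample identity, replicate index, treatment condition and
#' acceptor concentration (percent apoB-depleted serum; the assay's
#' standard working concentration is 2%).
#'
#' @param df Data frame with columns `plate_id`, `well` (e.g. `"A1"`),
#'   `role`, `sample_id`, `replicate`, `condition` (`"cAMP"` or
#'   `"no_cAMP"`), `acceptor_pct`. Wells not listed are `empty`.
#' @param wells_per_sample Required replicate count per sample (default 3);
#'   `NULL` skips the count check (non-standard designs).
#' @param check_roles If `TRUE` (default), enforce the control-well
#'   complement the full assay needs: >= 3 t0 controls, >= 3 passive
#'   wells, >= 3 unstained-background wells, >= 1 no-cell blank. Set
#'   `FALSE` for partial layouts.
#' @param require_correction If `TRUE`, additionally require exactly 4
#'   distinct correction-control samples and >= 2 distinct monitoring
#'   controls on the plate.
#' @return The validated layout data frame (class `cec_layout`).
#' @export
plate_layout <- function(df, wells_per_sample = 3, check_roles = TRUE,
                         require_correction = FALSE) {
  need <- c("plate_id", "well", "role", "sample_id", "replicate",
            "condition", "acceptor_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("layout lacks column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (length(unique(df$plate_id)) != 1)
    stopf("a layout describes exactly one plate, got plate_ids: %s",
          paste(unique(df$plate_id), collapse = ", "))
  bad <- setdiff(unique(df$role), WELL_ROLES)
  if (length(bad)) stopf("unknown well role(s): %s", paste(bad, collapse = ", "))
  ok_well <- grepl("^[A-H](1[0-2]|[1-9])$", df$well)
  if (!all(ok_well)) stopf("malformed well id(s): %s",
                           paste(unique(df$well[!ok_well]), collapse = ", "))
  if (anyDuplicated(df$well))
    stopf("well(s) assigned twice: %s",
          paste(unique(df$well[duplicated(df$well)]), collapse = ", "))

  samplish <- df[df$role %in% c("sample", "correction_control",
                                "monitoring_control"), ]
  if (nrow(samplish) && !is.null(wells_per_sample)) {
    cnt <- table(samplish$sample_id)
    off <- names(cnt)[cnt != wells_per_sample]
    if (length(off))
      stopf("sample '%s' has %d wells on plate '%s', expected %d",
            off[1], cnt[[off[1]]], df$plate_id[1], wells_per_sample)
  }
  if (check_roles) {
    need_role <- c(t0_control = 3, passive = 3, unstained_background = 3,
                   no_cell_blank = 1)
    for (r in names(need_role)) {
      n <- sum(df$role == r)
      if (n < need_role[[r]])
        stopf("layout for plate '%s' has %d '%s' well(s), needs >= %d",
              df$plate_id[1], n, r, need_role[[r]])
    }
  }
  if (require_correction) {
    ncc <- length(unique(df$sample_id[df$role == "correction_control"]))
    if (ncc != 4)
      stopf("plate correction needs exactly 4 correction-control samples, found %d", ncc)
    nmc <- length(unique(df$sample_id[df$role == "monitoring_control"]))
    if (nmc < 2)
      stopf("interassay monitoring needs >= 2 monitoring-control samples, found %d", nmc)
  }
  rownames(df) <- NULL
  class(df) <- c("cec_layout", "data.frame")
  df
}

#' Read / write a plate layout (long-format CSV)
#'
#' @param path File path.
#' @param ... Passed to [plate_layout()] (validation switches).
#' @return For `read_layout`, the validated layout; for `write_layout`,
#'   `path` invisibly.
#' @export
read_layout <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(plate_id = "character",
                                       well = "character",
                                       role = "character",
                                       sample_id = "character",
                                       condition = "character"))
  df$sample_id[is.na(df$sample_id)] <- ""
  df$replicate <- as.integer(df$replicate)
  df$acceptor_pct <- as.numeric(df$acceptor_pct)
  plate_layout(df, ...)
}

#' @rdname read_layout
#' @param layout A layout data frame.
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE, na = "")
  invisible(path)
}

well_index <- function(wells) {
  # row-major index of "A1".."H12" into the 8x12 matrix
  cbind(match(substr(wells, 1, 1), PLATE_ROWS),
        as.integer(substring(wells, 2)))
}

#' Join plate grids with a layout into raw well records
#'
#' Produces one record per non-empty well, carrying the raw readings of
#' every supplied read type. t0-control readings are taken from a `t0_fi`
#' grid when one is supplied, otherwise from the supernatant grid (the
#' usual case: t0 wells are lysed in place and captured by the same plate
#' read as the supernatants).
#'
#' @param grids List of [plate_grid()] objects for one plate (one per read
#'   type).
#' @param layout A [plate_layout()] for the same plate.
#' @param wells_per_sample Replicate count each sample must have
#'   (default 3; `NULL` to skip).
#' @return Data frame of raw well records: layout columns plus
#'   `fi_sup_raw`, `fi_lys_raw`, `a570_raw`, `a600_raw`, `gain_mismatch`.
#' @export
join_layout <- function(grids, layout, wells_per_sample = 3) {
  if (inherits(grids, "cec_plate_grid")) grids <- list(grids)
  layout <- plate_layout(layout, wells_per_sample = wells_per_sample,
                         check_roles = FALSE)
  pid <- layout$plate_id[1]
  types <- vapply(grids, function(g) g$read_type, character(1))
  if (anyDuplicated(types))
    stopf("duplicate grids for read type(s): %s",
          paste(unique(types[duplicated(types)]), collapse = ", "))
  for (g in grids) {
    if (!inherits(g, "cec_plate_grid")) stopf("grids must be plate_grid objects")
    if (!identical(g$plate_id, pid))
      stopf("grid plate_id '%s' does not match layout plate_id '%s'",
            g$plate_id, pid)
  }
  gr <- function(type) {
    i <- match(type, types)
    if (is.na(i)) return(NULL)
    grids[[i]]
  }
  sup <- gr("supernatant_fi"); lys <- gr("lysate_fi"); t0g <- gr("t0_fi")
  a570 <- gr("absorbance_570"); a600 <- gr("absorbance_600")

  gain_mismatch <- !is.null(sup) && !is.null(lys) &&
    !identical(sup$gain_tag, lys$gain_tag)
  if (gain_mismatch)
    warnf("plate '%s': supernatant gain '%s' differs from lysate gain '%s'",
          pid, sup$gain_tag, lys$gain_tag)

  rec <- layout[layout$role != "empty", , drop = FALSE]
  idx <- well_index(rec$well)
  pull <- function(g) if (is.null(g)) rep(NA_real_, nrow(rec)) else g$values[idx]
  rec$fi_sup_raw <- pull(sup)
  rec$fi_lys_raw <- pull(lys)
  if (!is.null(t0g)) {
    t0v <- pull(t0g)
    is_t0 <- rec$role == "t0_control"
    rec$fi_sup_raw[is_t0] <- t0v[is_t0]
  }
  rec$a570_raw <- pull(a570)
  rec$a600_raw <- pull(a600)
  rec$gain_mismatch <- gain_mismatch
  rownames(rec) <- NULL
  class(rec) <- "data.frame"
  rec
}

#' Read / write a run manifest
#'
#' A run manifest is a YAML file listing, for each plate, the grid file per
#' read type and the layout file. Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest path.
#' @return A list with one element per plate: `plate_id`, `grids` (named
#'   list of [plate_grid()]s) and `layout`.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$plates) || !length(m$plates))
    stopf("manifest %s lists no plates", path)
  base <- dirname(normalizePath(path))
  lapply(m$plates, function(p) {
    if (is.null(p$layout)) stopf("manifest plate entry lacks a layout file")
    grids <- lapply(unlist(p$grids, use.names = FALSE), function(f)
      read_plate_grid(file.path(base, f)))
    list(plate_id = p$plate_id %||% grids[[1]]$plate_id,
         grids = grids,
         layout = read_layout(file.path(base, p$layout),
                              wells_per_sample = NULL, check_roles = FALSE))
  })
}
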