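#' Read and write gridded velocity fields
#'
#' Two plain-text dialects are supported for steady fields.
#'
#' @section Delimited dialect (version 1):
#' Whitespace-separated ASCII, written byte-exactly as follows. Line 1:
#' `zoodrift-field 1`. Line 2: `ndim <d>` with d = 2 or 3. Line 3: `n`
#' followed by the d axis lengths. Lines 4..(3+d): the axis name (`x`, `y`,
#' `z`) followed by its coordinates in mm, `%.17g`-formatted. Next line:
#' `data` followed by the component names (`u v` or `u v w`). Then one line
#' per grid node holding the velocity components in mm/s (`%.17g`), nodes
#' ordered x-fastest (x innermost, then y, then z). `%.17g` preserves doubles
#' exactly, so a write/read cycle is bit-compatible.
#'
#' @section VTK dialect:
#' Legacy ASCII `DATASET RECTILINEAR_GRID` files with a `POINT_DATA` section
#' carrying `VECTORS velocity`. 2D fields are written with a single-point
#' z-axis (`DIMENSIONS nx ny 1`) and zero third component, and such files are
#' read back as 2D. Only this minimal dialect (as emitted by
#' `write_grid_field`) is understood; binary VTK and other dataset types are
#' not.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vtk"`.
#' @param field a steady [grid_velocity_field()].
#' @return `read_grid_field` returns a validated `grid_field`;
#'   `write_grid_field` returns `path` invisibly.
#' @export
read_grid_field <- function(path, format = c("delimited", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path))
    zd_stop(sprintf("file not found: %s", path), "invalid_argument")
  switch(format,
         delimited = read_field_delim(path),
         vtk = read_field_vtk(path))
}

#' @rdname read_grid_field
#' @export
write_grid_field <- function(field, path, format = c("delimited", "vtk")) {
  format <- match.arg(format)
  if (!inherits(field, "grid_field"))
    zd_stop("`field` must be a grid_field", "invalid_field")
  if (is_time_varying(field))
    zd_stop("file output supports steady fields only", "invalid_argument")
  switch(format,
         delimited = write_field_delim(field, path),
         vtk = write_field_vtk(field, path))
  invisible(path)
}

fmt_g <- function(x) sprintf("%.17g", x)

write_field_delim <- function(field, path) {
  con <- file(path, "wb")  # "wb": fixed \n line endings for bit-compatibility
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con, sep = "\n")
  ndim <- field$ndim
  wl("zoodrift-field 1")
  wl("ndim", ndim)
  wl("n", paste(lengths(field$axes), collapse = " "))
  for (j in seq_len(ndim))
    wl(names(field$axes)[j], paste(fmt_g(field$axes[[j]]), collapse = " "))
  wl("data", paste(COMP_NAMES[seq_len(ndim)], collapse = " "))
  flat <- vapply(field$components, as.vector, numeric(prod(lengths(field$axes))))
  rows <- apply(matrix(fmt_g(flat), ncol = ndim), 1, paste, collapse = " ")
  wl(paste(rows, collapse = "\n"))
}

read_field_delim <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) zd_stop(
    sprintf("parse error in %s line %d: %s", path, i, why), "parse")
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  if (length(lines) < 5L || !identical(tok[[1]], c("zoodrift-field", "1")))
    bad(1, "expected header 'zoodrift-field 1'")
  if (tok[[2]][1] != "ndim") bad(2, "expected 'ndim <d>'")
  ndim <- as.integer(tok[[2]][2])
  if (is.na(ndim) || !(ndim %in% c(2L, 3L))) bad(2, "ndim must be 2 or 3")
  if (tok[[3]][1] != "n" || length(tok[[3]]) != ndim + 1L)
    bad(3, sprintf("expected 'n' plus %d axis lengths", ndim))
  shape <- as.integer(tok[[3]][-1])
  if (anyNA(shape)) bad(3, "non-integer axis length")
  axes <- vector("list", ndim)
  for (j in seq_len(ndim)) {
    ln <- 3L + j
    if (tok[[ln]][1] != AXIS_NAMES[j])
      bad(ln, sprintf("expected axis '%s'", AXIS_NAMES[j]))
    ax <- suppressWarnings(as.numeric(tok[[ln]][-1]))
    if (length(ax) != shape[j] || anyNA(ax))
      zd_stop(sprintf("axis %s: %d coordinates found, header promises %d",
                      AXIS_NAMES[j], length(ax), shape[j]), "invalid_field")
    axes[[j]] <- ax
  }
  dl <- 4L + ndim
  if (tok[[dl]][1] != "data") bad(dl, "expected 'data' record")
  n_nodes <- prod(shape)
  body <- tok[seq.int(dl + 1L, length.out = length(lines) - dl)]
  body <- body[lengths(body) > 0L]
  vals <- suppressWarnings(as.numeric(unlist(body)))
  if (anyNA(vals)) bad(dl + 1L, "non-numeric velocity value in data block")
  if (length(vals) != n_nodes * ndim)
    zd_stop(sprintf(
      "data block has %d values; grid of %d nodes with %d components needs %d",
      length(vals), n_nodes, ndim, n_nodes * ndim), "invalid_field")
  m <- matrix(vals, ncol = ndim, byrow = TRUE)
  comps <- lapply(seq_len(ndim), function(k) array(m[, k], dim = shape))
  grid_velocity_field(axes, comps)
}

write_field_vtk <- function(field, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con, sep = "\n")
  ndim <- field$ndim
  axes <- field$axes
  if (ndim == 2L) axes$z <- 0
  shape <- lengths(axes)
  wl("# vtk DataFile Version 3.0")
  wl("zoodrift velocity field")
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS ", paste(shape, collapse = " "))
  for (j in 1:3) {
    wl(toupper(AXIS_NAMES[j]), "_COORDINATES ", shape[j], " double")
    wl(paste(fmt_g(axes[[j]]), collapse = " "))
  }
  n_nodes <- prod(shape)
  wl("POINT_DATA ", n_nodes)
  wl("VECTORS velocity double")
  flat <- vapply(field$components, as.vector, numeric(n_nodes))
  if (ndim == 2L) flat <- cbind(flat, 0)
  rows <- apply(matrix(fmt_g(flat), ncol = 3L), 1, paste, collapse = " ")
  wl(paste(rows, collapse = "\n"))
}

read_field_vtk <- function(path) {
  lines <- readLines(path)
  toks <- unlist(strsplit(trimws(lines[-(1:2)]), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  pos <- 1L
  need <- function(what) {
    if (pos > length(toks) || toupper(toks[pos]) != what)
      zd_stop(sprintf("parse error in %s: expected '%s' near token %d ('%s')",
                      path, what, pos,
                      if (pos <= length(toks)) toks[pos] else "<eof>"), "parse")
    pos <<- pos + 1L
  }
  take_num <- function(n, what) {
    v <- suppressWarnings(as.numeric(toks[seq.int(pos, length.out = n)]))
    if (length(v) != n || anyNA(v))
      zd_stop(sprintf("parse error in %s: bad numeric block for %s", path, what),
              "parse")
    pos <<- pos + n
    v
  }
  need("ASCII"); need("DATASET"); need("RECTILINEAR_GRID"); need("DIMENSIONS")
  shape <- as.integer(take_num(3, "DIMENSIONS"))
  axes <- vector("list", 3)
  for (j in 1:3) {
    need(paste0(toupper(AXIS_NAMES[j]), "_COORDINATES"))
    pos <- pos + 2L  # count and dtype tokens
    axes[[j]] <- take_num(shape[j], paste0(AXIS_NAMES[j], " coordinates"))
  }
  need("POINT_DATA")
  n_nodes <- as.integer(take_num(1, "POINT_DATA count"))
  if (n_nodes != prod(shape))
    zd_stop(sprintf("POINT_DATA count %d does not match grid size %d",
                    n_nodes, prod(shape)), "invalid_field")
  need("VECTORS")
  if (tolower(toks[pos]) != "velocity")
    zd_stop(sprintf("expected vector field named 'velocity', found '%s'",
                    toks[pos]), "parse")
  pos <- pos + 2L  # name and dtype
  vals <- take_num(n_nodes * 3L, "velocity vectors")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  if (shape[3] == 1L) {  # 2D field stored with a singleton z axis
    comps <- lapply(1:2, function(k) array(m[, k], dim = shape[1:2]))
    grid_velocity_field(axes[1:2], comps)
  } else {
    comps <- lapply(1:3, function(k) array(m[, k], dim = shape))
    grid_velocity_field(axes, comps)
  }
}
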