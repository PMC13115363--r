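#' Electrode layouts on the topographic grid
#'
#' EEG channels are arranged on a sparse 2-D grid that preserves the relative
#' scalp positions of the electrodes; grid cells without an electrode stay
#' zero when features are mapped onto the grid.  A layout is the channel ->
#' (row, col) assignment for an `grid_rows` x `grid_cols` grid (8 x 9 for the
#' 32-channel montage shipped with the package).
#'
#' @param entries data.frame with columns `channel` (character), `row`, `col`
#'   (0-based integer grid indices).
#' @param grid_rows,grid_cols grid dimensions.
#' @return An object of class `electrode_layout`.
#' @seealso [load_layout()], [map_to_grid()]
#' @export
electrode_layout <- function(entries, grid_rows = 8L, grid_cols = 9L) {
  stopifnot(is.data.frame(entries),
            all(c("channel", "row", "col") %in% names(entries)))
  entries$channel <- as.character(entries$channel)
  entries$row <- as.integer(entries$row)
  entries$col <- as.integer(entries$col)
  bad <- entries$row < 0L | entries$row >= grid_rows |
         entries$col < 0L | entries$col >= grid_cols
  if (any(bad))
    stop("layout entries outside the ", grid_rows, "x", grid_cols, " grid: ",
         paste(entries$channel[bad], collapse = ", "))
  key <- paste(entries$row, entries$col)
  if (anyDuplicated(key))
    stop("duplicate grid positions: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(entries$channel))
    stop("duplicate channel names: ",
         paste(unique(entries$channel[duplicated(entries$channel)]),
               collapse = ", "))
  structure(list(entries = entries,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols)),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("Electrode layout:", nrow(x$entries), "channels on an",
      x$grid_rows, "x", x$grid_cols, "grid\n")
  invisible(x)
}

#' Read an electrode layout file
#'
#' Plain-text format, one electrode per line: `name row col` with 0-based
#' grid indices; blank lines and `#` comments are ignored.
#'
#' @param path path to a layout file.
#' @param grid_rows,grid_cols grid dimensions the entries must fit in.
#' @return An [electrode_layout()].
#' @examples
#' p <- system.file("extdata", "deap_32.layout", package = "msdafuse")
#' lay <- load_layout(p)
#' nrow(lay$entries)  # 32
#' @export
load_layout <- function(path, grid_rows = 8L, grid_cols = 9L) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(stripped)))
  entries <- data.frame(channel = character(0), row = integer(0),
                        col = integer(0))
  for (i in keep) {
    tok <- strsplit(trimws(stripped[i]), "[[:space:]]+")[[1]]
    if (length(tok) != 3L || anyNA(suppressWarnings(as.integer(tok[2:3]))))
      stop("malformed layout line ", i, ": '", raw[i], "'")
    entries <- rbind(entries, data.frame(channel = tok[1],
                                         row = as.integer(tok[2]),
                                         col = as.integer(tok[3])))
  }
  electrode_layout(entries, grid_rows, grid_cols)
}

#' Write an electrode layout file
#'
#' Inverse of [load_layout()]: writes the `name row col` lines so that
#' reading the file back reproduces the entry set exactly.
#'
#' @param layout an [electrode_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "electrode_layout"))
  lines <- sprintf("%s %d %d", layout$entries$channel,
                   layout$entries$row, layout$entries$col)
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 32-channel layout
#'
#' Convenience accessor for the 8 x 9 grid placement of the standard
#' 32-electrode montage shipped in `extdata`.
#'
#' @return An [electrode_layout()] with 32 entries.
#' @export
deap_layout <- function() {
  load_layout(system.file("extdata", "deap_32.layout", package = "msdafuse"))
}
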