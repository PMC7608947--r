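# Whisker identity conventions and the sandpaper grade table.

GREEK_WHISKERS <- c("alpha", "beta", "gamma", "delta")
WHISKER_ROWS <- c("A", "B", "C", "D", "E")

#' Whisker identity
#'
#' Canonical identity of a macrovibrissa on the mystacial pad. Whiskers are
#' indexed by row (A-E, dorsal to ventral) and arc (column, caudal to
#' rostral). The four long Greek whiskers (alpha-delta) form the caudal-most
#' column and are modeled as arc 0 with row label `"Greek"`; arcs 1-4 carry
#' standard names such as `"C2"`. Parsing and formatting round-trip over all
#' canonical names.
#'
#' @param name Canonical whisker name: `"A1"`..`"E4"` or a Greek name
#'   (`"alpha"`, `"beta"`, `"gamma"`, `"delta"`, case-insensitive).
#' @param side `"left"` or `"right"`.
#' @return An object of class `whisker_id` with fields `row`, `arc`, `side`
#'   and the canonical `name`.
#' @examples
#' whisker_id("C2")
#' whisker_id("gamma")$arc   # Greek column is arc 0
#' @export
whisker_id <- function(name, side = c("left", "right")) {
  if (inherits(name, "whisker_id")) return(name)
  side <- match.arg(side)
  if (!is.character(name) || length(name) != 1L || is.na(name))
    wp_abort("whisker name must be a single character string")
  nm <- tolower(trimws(name))
  if (nm %in% GREEK_WHISKERS) {
    row <- "Greek"
    arc <- 0L
    canonical <- nm
  } else if (grepl("^[a-eA-E][1-4]$", nm)) {
    row <- toupper(substr(nm, 1L, 1L))
    arc <- as.integer(substr(nm, 2L, 2L))
    canonical <- paste0(row, arc)
  } else {
    wp_abort(sprintf(
      "unknown whisker name '%s' (expected A1..E4 or alpha/beta/gamma/delta)",
      name))
  }
  structure(list(row = row, arc = arc, side = side, name = canonical),
            class = "whisker_id")
}

#' @export
format.whisker_id <- function(x, ...) x$name

#' @export
print.whisker_id <- function(x, ...) {
  cat(sprintf("<whisker %s: row %s, arc %d, %s side>\n",
              x$name, x$row, x$arc, x$side))
  invisible(x)
}

#' @export
as.character.whisker_id <- function(x, ...) x$name

#' All canonical whisker names
#'
#' @param greek Include the Greek (arc-0) whiskers.
#' @return Character vector of canonical names.
#' @export
all_whisker_names <- function(greek = TRUE) {
  std <- as.vector(outer(WHISKER_ROWS, 1:4, paste0))
  if (greek) c(GREEK_WHISKERS, std) else std
}

#' Sandpaper texture grades
#'
#' The seven P-grade sandpapers used as texture stimuli, with their mean
#' particle diameters. Diameter decreases strictly with increasing P-number
#' (larger P-number = finer grain).
#'
#' @return A data.frame with columns `grade`, `p_number` and `diameter_um`.
#' @examples
#' texture_grades()
#' @export
texture_grades <- function() {
  data.frame(
    grade = c("P120", "P150", "P220", "P400", "P600", "P800", "P1200"),
    p_number = c(120L, 150L, 220L, 400L, 600L, 800L, 1200L),
    diameter_um = c(125, 100, 68, 35, 26, 22, 15),
    stringsAsFactors = FALSE
  )
}

#' Look up a single texture grade
#'
#' @param grade Grade label (e.g. `"P220"`) or a list with fields `grade` and
#'   `diameter_um` for custom conditions.
#' @return A list with fields `grade` and `diameter_um`.
#' @export
texture_grade <- function(grade) {
  if (is.list(grade)) {
    if (is.null(grade$grade) || is.null(grade$diameter_um))
      wp_abort("a custom condition needs fields 'grade' and 'diameter_um'")
    return(list(grade = as.character(grade$grade),
                diameter_um = as.numeric(grade$diameter_um)))
  }
  tab <- texture_grades()
  i <- match(toupper(grade), tab$grade)
  if (is.na(i))
    wp_abort(sprintf("unknown texture grade '%s'", grade))
  list(grade = tab$grade[i], diameter_um = tab$diameter_um[i])
}
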