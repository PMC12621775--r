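# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of plain DNA strings
#'
#' Vectorized reverse complement over character vectors (A/C/G/T/N).
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    rc_string_cpp(s)
  }, character(1), USE.NAMES = FALSE)
  out
}

# Stop with a classed condition so callers/tests can match on class.
pm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "panmap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run code with a temporarily fixed RNG seed, restoring global state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Orientation helpers: orientation is stored as +1L (forward) / -1L (reverse).
orient_chr <- function(o) ifelse(o > 0L, "+", "-")
chr_orient <- function(ch) ifelse(ch %in% c("+", ">"), 1L, -1L)

# Oriented-vertex labels used by the distance machinery: "12+" / "12-".
ov_label <- function(node, orient) paste0(node, ifelse(orient > 0L, "+", "-"))
ov_flip <- function(lab) {
  n <- nchar(lab)
  paste0(substr(lab, 1L, n - 1L), ifelse(substr(lab, n, n) == "+", "-", "+"))
}
ov_node <- function(lab) as.integer(substr(lab, 1L, nchar(lab) - 1L))
ov_orient <- function(lab) ifelse(substr(lab, nchar(lab), nchar(lab)) == "+", 1L, -1L)
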