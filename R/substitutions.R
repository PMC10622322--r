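#' Amino acid alphabet used throughout the package
#'
#' The 20 standard residues. Records containing anything else (X, B, Z, U,
#' ...) are kept in the database, but peptides touching a non-standard
#' residue are excluded from digestion output.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Parse substitution strings
#'
#' Substitutions are written in the conventional `posREF>ALT` form, e.g.
#' `"527D>E"`, with the position 1-based on the parent protein. Several
#' substitutions on one haplotype are `;`-joined: `"527D>E;532K>E"`.
#'
#' @param x Character vector of `;`-joined substitution strings. `NA` and
#'   `""` denote an empty substitution set.
#' @return A list (one element per input string) of data frames with columns
#'   `position` (integer, 1-based), `ref` and `alt` (single residues).
#' @examples
#' parse_substitutions("527D>E;532K>E")
#' @export
parse_substitutions <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(
        position = integer(0), ref = character(0), alt = character(0),
        stringsAsFactors = FALSE
      ))
    }
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    m <- regmatches(parts, regexec("^([0-9]+)([A-Za-z\\*])>([A-Za-z\\*])$", parts))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) {
      stop("malformed substitution string(s): ",
           paste(parts[bad], collapse = ", "))
    }
    out <- data.frame(
      position = as.integer(vapply(m, `[`, "", 2L)),
      ref = toupper(vapply(m, `[`, "", 3L)),
      alt = toupper(vapply(m, `[`, "", 4L)),
      stringsAsFactors = FALSE
    )
    if (any(out$ref == out$alt)) {
      stop("substitution with identical ref and alt residue: ",
           paste(parts[out$ref == out$alt], collapse = ", "))
    }
    if (anyDuplicated(out$position)) {
      stop("duplicated substitution positions in '", s, "'")
    }
    out[order(out$position), , drop = FALSE]
  })
}

#' Format substitutions back to `posREF>ALT` notation
#'
#' @param subs A data frame with columns `position`, `ref`, `alt` (as
#'   returned by [parse_substitutions()]).
#' @return A single `;`-joined string (`""` for an empty set).
#' @export
format_substitutions <- function(subs) {
  if (is.null(subs) || nrow(subs) == 0L) return("")
  subs <- subs[order(subs$position), , drop = FALSE]
  paste0(subs$position, subs$ref, ">", subs$alt, collapse = ";")
}

# number of substitutions encoded by a `;`-joined string, vectorised
count_substitutions <- function(x) {
  x <- as.character(x)
  n <- integer(length(x))
  has <- !is.na(x) & nzchar(x)
  n[has] <- vapply(strsplit(x[has], ";", fixed = TRUE),
                   function(p) sum(nzchar(p)), 1L)
  n
}
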