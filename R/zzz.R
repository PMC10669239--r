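#' @useDynLib mmphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.onLoad <- function(libname, pkgname) {
  # the four diagnostic domain-family sets must be pairwise disjoint and
  # complete (9 + 2 + 1 + 1 identifiers)
  map <- domain_family_map()
  ids <- unlist(map, use.names = FALSE)
  stopifnot(!anyDuplicated(ids),
            lengths(map)[c("matrixin", "hemopexin", "pg_binding",
                           "fibronectin")] == c(9L, 2L, 1L, 1L))
  invisible()
}
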