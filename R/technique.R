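TECHNIQUES <- c("ribose-seq", "HydEn-seq", "Pu-seq", "emRiboSeq")

#' Parse an rNMP sequencing technique name
#'
#' Case-insensitive; accepts the four supported techniques. HydEn-seq and
#' Pu-seq share identical coordinate arithmetic downstream.
#'
#' @param x Technique name (any case).
#' @return Canonical technique string.
#' @export
parse_technique <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  hit <- match(tolower(x), tolower(TECHNIQUES))
  if (is.na(hit)) {
    stop("unknown technique '", x, "'; expected one of: ",
         paste(TECHNIQUES, collapse = ", "), call. = FALSE)
  }
  TECHNIQUES[hit]
}

# Internal seed guard: set a seed for the duration of the calling frame and
# restore the caller's RNG state afterwards.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible()
}
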