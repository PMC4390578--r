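# Pluggable similarity scorers. A scorer maps an aligned_pair to a value in
# [0, 1]; percent identity ("perID") is the default. User-defined scorers
# (e.g. substitution-matrix or profile-HMM based) register under a name and
# become selectable wherever a scorer is accepted.

.scorer_registry <- new.env(parent = emptyenv())

#' Register a similarity scorer
#'
#' A scorer is any function taking an [aligned_pair()] and returning either a
#' number in `[0, 1]` or a `similarity_score`. Registered scorers can be
#' referred to by name throughout the integration pipeline; `"perID"`
#' (reference-denominated percent identity) is registered by default.
#'
#' @param name Scorer name.
#' @param fn The scoring function.
#' @return `name`, invisibly.
#' @examples
#' register_scorer("coverage", function(pair) {
#'   k <- strsplit(pair$cand, "")[[1]]
#'   r <- strsplit(pair$ref, "")[[1]]
#'   sum(r != "-" & k != "-") / sum(r != "-")
#' })
#' "coverage" %in% list_scorers()
#' @export
register_scorer <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(fn))
  assign(name, fn, envir = .scorer_registry)
  invisible(name)
}

#' @rdname register_scorer
#' @export
list_scorers <- function() sort(ls(.scorer_registry))

#' Resolve a scorer by name
#'
#' @param scorer A scorer name or a scoring function (returned unchanged).
#' @return A scoring function.
#' @rdname register_scorer
#' @export
get_scorer <- function(scorer = "perID") {
  if (is.function(scorer)) return(scorer)
  stopifnot(is.character(scorer), length(scorer) == 1L)
  if (!exists(scorer, envir = .scorer_registry, inherits = FALSE)) {
    stop("unknown scorer '", scorer, "'; registered: ",
         paste(list_scorers(), collapse = ", "), call. = FALSE)
  }
  get(scorer, envir = .scorer_registry, inherits = FALSE)
}

# Extract a bare numeric score from whatever a scorer returned.
.score_value <- function(x) {
  v <- if (inherits(x, "similarity_score")) x$value else x
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
    stop("scorer must return a single value in [0, 1]", call. = FALSE)
  }
  as.numeric(v)
}

.onLoad <- function(libname, pkgname) {
  register_scorer("perID", function(pair) percent_identity(pair)$value)
}

# also register when the package is loaded without .onLoad (e.g. sourcing)
register_scorer("perID", function(pair) percent_identity(pair)$value)
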