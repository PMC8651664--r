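#' @keywords internal
"_PACKAGE"

# Internal argument checks ----------------------------------------------------

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("qdrlart_domain_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("qdrlart_config_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("qdrlart_schema_error", "error")))
}

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_domain(name, " must be a single finite number")
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  assert_scalar_num(x, name)
  if (x < 0 || x > 1) stop_domain(name, " must lie in [0, 1], got ", x)
  invisible(x)
}

#' Hash a configuration object
#'
#' Stable hash of an R object (typically a nested configuration list), used to
#' stamp every artifact a pipeline run writes so results can be traced back to
#' the exact configuration that produced them.
#'
#' @param x Any R object.
#' @return A character scalar hash.
#' @export
config_hash <- function(x) {
  rlang::hash(x)
}
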