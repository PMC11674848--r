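#' @useDynLib adtrx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# as.character that keeps names (plain as.character drops them on
# character input)
as_named_chr <- function(x) {
    nm <- names(x)
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- nm
    out
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_local_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegating to
#' \code{stats::p.adjust}, method "BH"), with input validation. Output
#' order matches input order.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
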