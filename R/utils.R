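`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed radsurv error
#' @noRd
radsurv_abort <- function(message, class) {
  cond <- structure(
    class = c(class, "radsurv_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

#' Derive a stream seed from a master seed
#'
#' Deterministic integer mixing so that each pipeline stage / CV repeat gets
#' its own reproducible seed from one master seed. Result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stream = 0L) {
  m <- (as.double(master) %% 2147483647) + 1
  s <- (as.double(stream) %% 2147483647)
  v <- (m * 48271 + s * 16807 + 12345) %% 2147483646
  as.integer(v) + 1L
}

stopifnot_same_shape <- function(a, b, what = "arrays") {
  if (!identical(dim(a), dim(b))) {
    radsurv_abort(
      sprintf("%s have mismatched shapes: %s vs %s", what,
              paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
      "radsurv_error_shape"
    )
  }
  invisible(TRUE)
}
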