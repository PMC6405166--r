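#' Izhikevich neuron parameter registry
#'
#' Returns the parameter set for one of the named cell presets used throughout
#' the circuit models: the regular-spiking (RS) source and target neurons and
#' the fast-spiking (FS) interneuron. Two target variants exist: the
#' subthreshold variant used in the single and coupled circuits
#' (`"Tgt_subthreshold"`: C = 100 pF, v_t = -40 mV) and the network variant
#' (`"Tgt_network"`) with halved capacitance (50 pF) and a lowered spike
#' threshold (-45 mV) so that a single source spike reliably drives a target
#' spike. The registry is stored as a plain JSON file under
#' `inst/extdata/izhikevich_params.json` so the presets can be audited and
#' replayed exactly.
#'
#' @param cell One of `"Src"`, `"Int"`, `"Tgt_subthreshold"`, `"Tgt_network"`.
#' @return An object of class `izh_params`: a list with `cell_type` (`"RS"` or
#'   `"FS"`) and numeric entries `C` (pF), `v_r`, `v_t`, `v_p` (mV), `k` (nS),
#'   `a` (1/ms), `b` (nS), `c` (mV), `d` (pA) and, for FS cells, `v_b` (mV).
#' @export
#' @examples
#' izhikevich_params("Int")$C  # 20 pF
izhikevich_params <- function(cell = c("Src", "Int", "Tgt_subthreshold", "Tgt_network")) {
  cell <- match.arg(cell)
  reg <- izh_registry()
  p <- reg[[cell]]
  p$preset <- cell
  if (is.null(p$v_b)) p$v_b <- NA_real_
  class(p) <- "izh_params"
  validate_izh_params(p)
  p
}

# registry cache (read once per session)
izh_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "izhikevich_params.json", package = "ffinet")
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})

validate_izh_params <- function(p) {
  num <- c("C", "v_r", "v_t", "v_p", "k", "a", "c", "d")
  for (f in num) {
    if (!is.numeric(p[[f]]) || !is.finite(p[[f]]))
      stop("parameter '", f, "' must be a finite number")
  }
  stopifnot(p$C > 0, p$v_r < p$v_t, p$v_t < p$v_p, p$c < p$v_p)
  if (identical(p$cell_type, "FS")) {
    if (!is.finite(p$v_b)) stop("FS parameters require v_b")
  }
  invisible(p)
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("<izh_params: %s (%s)>\n", x$preset, x$cell_type))
  flds <- setdiff(names(x), c("cell_type", "preset"))
  cat(paste(sprintf("  %s = %g", flds, unlist(x[flds])), collapse = "\n"), "\n")
  invisible(x)
}

#' Membrane potential derivative
#'
#' Rate of change of the membrane potential `v` (mV/ms):
#' `dv/dt = (k (v - v_r)(v - v_t) - u + I_app + I_syn) / C`.
#'
#' @param v Membrane potential (mV).
#' @param u Recovery current (pA).
#' @param params An `izh_params` object.
#' @param I_app Applied current (pA): holding plus stimulus.
#' @param I_syn Total synaptic current (pA).
#' @return dv/dt in mV/ms. Vectorised over `v`, `u` and the currents.
#' @export
membrane_rhs <- function(v, u, params, I_app = 0, I_syn = 0) {
  if (!all(is.finite(v), is.finite(u), is.finite(I_app), is.finite(I_syn)))
    stop("non-finite state or current")
  (params$k * (v - params$v_r) * (v - params$v_t) - u + I_app + I_syn) / params$C
}

#' Recovery current derivative
#'
#' Rate of change of the recovery current `u` (pA/ms). For RS cells
#' `du/dt = a (b (v - v_r) - u)`; for FS cells `du/dt = a (U(v) - u)` with
#' `U(v) = 0` below `v_b` and `b (v - v_b)^3` above it.
#'
#' @inheritParams membrane_rhs
#' @return du/dt in pA/ms.
#' @export
recovery_rhs <- function(v, u, params) {
  if (!all(is.finite(v), is.finite(u))) stop("non-finite state")
  if (identical(params$cell_type, "FS")) {
    U <- ifelse(v < params$v_b, 0, params$b * (v - params$v_b)^3)
    params$a * (U - u)
  } else {
    params$a * (params$b * (v - params$v_r) - u)
  }
}

#' Spike detection and reset
#'
#' Applies the discontinuous reset: whenever `v >= v_p`, set `v <- c` and
#' `u <- u + d` and flag a spike. Called on the candidate state after each
#' Euler step.
#'
#' @inheritParams membrane_rhs
#' @return A list with elements `v`, `u` (post-reset) and logical `spiked`.
#' @export
apply_reset <- function(v, u, params) {
  spiked <- v >= params$v_p
  list(v = ifelse(spiked, params$c, v),
       u = ifelse(spiked, u + params$d, u),
       spiked = spiked)
}
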