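#' Configuration of the agent-based homogenization phase
#'
#' Every pixel is an agent holding one of 256 intensity states. In each
#' sweep, agents are visited row by row from the top, right to left
#' within each row, and each agent moves its intensity by `delta`
#' toward the sign consensus of its neighborhood.
#'
#' The default update scheme is synchronous: every consensus value is
#' computed from the pre-sweep grid. A sequential (in-place,
#' Gauss-Seidel) variant is available, but it is unstable: an agent
#' lowered early in a sweep immediately biases every later agent in
#' scan order, so a single defect cascades across the grid within one
#' sweep and distinct regions drift toward a common gray level instead
#' of homogenizing separately.
#'
#' The defaults couple the step to the iteration budget: a defect of
#' height `h` needs `ceiling(h / delta)` sweeps to be absorbed, so full
#' 8-bit impulses (height up to 255) are removable within `iter1`
#' sweeps only when `delta * iter1 >= 255`; `delta = 3` with
#' `iter1 = 100` is the smallest integer step meeting that with a
#' margin.
#'
#' @param iter1 number of sweeps, `>= 0`.
#' @param delta intensity step per update, integer `>= 1`.
#' @param neighborhood `"moore"` (8 neighbors, default) or
#'   `"von-neumann"` (4 cardinal neighbors).
#' @param scan_order `"right-to-left"` (default) or `"left-to-right"`
#'   within each row; rows always run top to bottom. Only observable
#'   with sequential updates.
#' @param update `"synchronous"` (default) or `"sequential"` (agents
#'   updated earlier in the sweep expose their new state to later
#'   agents).
#' @return an object of class `"abm_config"`.
#' @export
abm_config <- function(iter1 = 100L, delta = 3L,
                       neighborhood = c("moore", "von-neumann"),
                       scan_order = c("right-to-left", "left-to-right"),
                       update = c("synchronous", "sequential")) {
  if (iter1 < 0) stop("`iter1` must be >= 0", call. = FALSE)
  if (delta < 1 || delta != floor(delta)) {
    stop("`delta` must be an integer >= 1", call. = FALSE)
  }
  structure(list(iter1 = as.integer(iter1), delta = as.integer(delta),
                 neighborhood = match.arg(neighborhood),
                 scan_order = match.arg(scan_order),
                 update = match.arg(update)),
            class = "abm_config")
}

#' Sign consensus of one agent's neighborhood
#'
#' Computes `S = sign(sum_q sign(e_q - e_0))` over the neighbors `e_q`
#' of pixel `(i, j)` that lie inside the grid (5 at edges, 3 at corners
#' for the Moore neighborhood). `S = +1` means the neighborhood
#' majority is brighter than the agent, `S = -1` darker, and `S = 0`
#' marks either a uniform patch or an evenly split (edge) neighborhood.
#'
#' @param image grayscale matrix.
#' @param i,j row and column of the agent (1-based).
#' @param neighborhood `"moore"` or `"von-neumann"`.
#' @return `-1`, `0`, or `+1`.
#' @export
neighbor_consensus <- function(image, i, j,
                               neighborhood = c("moore", "von-neumann")) {
  image <- as_gray_image(image)
  neighborhood <- match.arg(neighborhood)
  if (i < 1 || i > nrow(image) || j < 1 || j > ncol(image)) {
    stop("agent index out of bounds", call. = FALSE)
  }
  e0 <- image[i, j]
  acc <- 0L
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    if (neighborhood == "von-neumann" && di != 0L && dj != 0L) next
    ni <- i + di; nj <- j + dj
    if (ni < 1 || ni > nrow(image) || nj < 1 || nj > ncol(image)) next
    acc <- acc + sign(image[ni, nj] - e0)
  }
  as.integer(sign(acc))
}

#' Apply one consensus rule to a single agent state
#'
#' `S = +1` raises the state by `delta`, `S = -1` lowers it, `S = 0`
#' leaves it unchanged; the result is clamped to `[0, 255]`.
#'
#' @param state current intensity in `[0, 255]`.
#' @param s consensus value in `{-1, 0, +1}`.
#' @param delta intensity step, `>= 1`.
#' @return the updated state.
#' @export
apply_rule <- function(state, s, delta = 1L) {
  stopifnot(s %in% c(-1L, 0L, 1L), delta >= 1)
  clamp(state + s * delta)
}

#' One sweep of the agent-based model
#'
#' Visits every agent once in the configured scan order and applies the
#' consensus rules. With sequential updates (the default), an agent
#' updated earlier in the sweep exposes its new intensity to agents
#' visited later.
#'
#' @param image grayscale matrix.
#' @param config an [abm_config()]; its `iter1` is ignored here.
#' @return the swept image, same shape.
#' @export
abm_step <- function(image, config = abm_config()) {
  image <- as_gray_image(image)
  .abm_sweep(image, config$delta,
             config$neighborhood == "moore",
             config$scan_order == "right-to-left",
             config$update == "sequential")
}

#' Run the agent-based homogenization phase
#'
#' Applies [abm_step()] `iter1` times. With `trace = TRUE` the returned
#' image carries a `"variance"` attribute: the grid intensity variance
#' after every sweep (element 1 is the input image), a cheap
#' convergence diagnostic that decreases as regions homogenize.
#'
#' @param image grayscale matrix.
#' @param config an [abm_config()].
#' @param trace record per-sweep grid variance?
#' @return the homogenized image; with `trace = TRUE`, the variance
#'   trace is attached as attribute `"variance"`.
#' @examples
#' im <- matrix(200L, 5, 5); im[3, 3] <- 0L
#' run_abm(im, abm_config(iter1 = 50, delta = 1))[3, 3]  # climbed 50 so far
#' @export
run_abm <- function(image, config = abm_config(), trace = FALSE) {
  image <- as_gray_image(image)
  res <- .abm_run(image, config$iter1, config$delta,
                  config$neighborhood == "moore",
                  config$scan_order == "right-to-left",
                  config$update == "sequential", trace)
  out <- res$image
  if (trace) attr(out, "variance") <- res$variance
  out
}
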