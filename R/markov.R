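#' Post-Albers state labels
#'
#' The four principal conformations of the Na/K-ATPase transport cycle, in
#' cycle order: `E1 -> E1P -> E2P -> E2 -> E1`.
#'
#' @return Character vector of the four core state labels.
#' @export
#' @examples
#' post_albers_states()
post_albers_states <- function() c("E1", "E1P", "E2P", "E2")

#' Construct a state space
#'
#' A state space is an ordered set of unique conformational-state labels.
#' Hidden states (e.g. sub-states binding different numbers of Na or K ions)
#' may be tracked separately so that marginalisation back to the visible
#' states is well defined.
#'
#' @param labels Character vector of unique, non-empty state names.
#' @param hidden Optional character vector naming which of `labels` are
#'   hidden (interleaved) states.
#' @return A `state_space` object (character vector with a `hidden`
#'   attribute).
#' @export
state_space <- function(labels = post_albers_states(), hidden = character()) {
  labels <- as.character(labels)
  if (length(labels) == 0 || anyNA(labels) || any(!nzchar(labels))) {
    abort("state labels must be non-empty strings", class = "pumploop_structural_error")
  }
  if (anyDuplicated(labels)) {
    abort("state labels must be unique", class = "pumploop_structural_error")
  }
  hidden <- as.character(hidden)
  if (!all(hidden %in% labels)) {
    abort("hidden states must be a subset of the labels", class = "pumploop_structural_error")
  }
  structure(labels, hidden = hidden, class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", paste(unclass(x), collapse = " -> "), "\n", sep = "")
  h <- attr(x, "hidden")
  if (length(h)) cat("  hidden: ", paste(h, collapse = ", "), "\n", sep = "")
  invisible(x)
}

visible_states <- function(states) {
  setdiff(unclass(states), attr(states, "hidden") %||% character())
}

#' Construct a one-step transition matrix
#'
#' Wraps a row-stochastic matrix of one-step conformational transition
#' probabilities `p_ij = P(X_{n+1} = j | X_n = i)` over a state space, with a
#' nominal (arbitrary-unit) time step `dt` carried as metadata.
#'
#' @param P Square numeric matrix of transition probabilities; rows must sum
#'   to 1.
#' @param states A [state_space()] (or character vector of labels). Defaults
#'   to the matrix dimnames, or the Post-Albers labels for an unnamed 4x4
#'   matrix, or `S1..Sn` otherwise.
#' @param dt Nominal time interval per step (arbitrary units).
#' @param tol Row-sum / negativity tolerance used for construction-time
#'   validation.
#' @return A `transition_matrix` object.
#' @seealso [validate_transition_matrix()] for a non-throwing report.
#' @export
#' @examples
#' transition_matrix(default_post_albers_matrix())
transition_matrix <- function(P, states = NULL, dt = 1, tol = 1e-9) {
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) != ncol(P)) {
    abort("P must be a square numeric matrix", class = "pumploop_structural_error")
  }
  if (is.null(states)) {
    states <- if (!is.null(rownames(P))) {
      state_space(rownames(P))
    } else if (nrow(P) == 4) {
      state_space(post_albers_states())
    } else {
      state_space(paste0("S", seq_len(nrow(P))))
    }
  }
  if (!inherits(states, "state_space")) states <- state_space(states)
  if (length(states) != nrow(P)) {
    abort("dimension of P must equal the number of states",
          class = "pumploop_structural_error")
  }
  dimnames(P) <- list(unclass(states), unclass(states))
  rep <- validate_transition_matrix(P, tol = tol)
  if (!rep$pass) {
    abort(paste0("matrix is not row-stochastic; offending rows: ",
                 paste(rep$report$state[!rep$report$ok], collapse = ", ")),
          class = "pumploop_validation_error")
  }
  structure(P, states = states, dt = dt, class = c("transition_matrix", "matrix"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", nrow(x), " states, dt = ", attr(x, "dt"), "\n", sep = "")
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "states") <- NULL
  attr(x, "dt") <- NULL
  class(x) <- NULL
  x
}

tm_states <- function(P) {
  attr(P, "states") %||% state_space(rownames(P) %||% paste0("S", seq_len(nrow(P))))
}

#' Validate a candidate one-step transition matrix
#'
#' Checks squareness, entry-wise bounds and row stochasticity without
#' throwing on probabilistic violations: structural problems (non-square
#' input) are errors, while negative entries or row sums off 1 yield a
#' failing report listing the offending rows.
#'
#' @param P Numeric matrix (or `transition_matrix`).
#' @param tol Maximum tolerated absolute row-sum deviation and entry
#'   negativity (default `1e-9`).
#' @return A `tm_validation` list with elements `pass` (logical) and
#'   `report`, a tibble with one row per state: `state`, `row_sum`,
#'   `deviation`, `min_entry`, `ok`.
#' @export
#' @examples
#' validate_transition_matrix(diag(4))
validate_transition_matrix <- function(P, tol = 1e-9) {
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) != ncol(P)) {
    abort("P must be a square numeric matrix", class = "pumploop_structural_error")
  }
  labels <- rownames(P) %||% paste0("S", seq_len(nrow(P)))
  rs <- rowSums(P)
  report <- tibble(
    state     = labels,
    row_sum   = rs,
    deviation = abs(rs - 1),
    min_entry = apply(P, 1, min),
    ok        = abs(rs - 1) <= tol & apply(P, 1, min) >= -tol & apply(P, 1, max) <= 1 + tol
  )
  structure(list(pass = all(report$ok), report = report, tol = tol),
            class = "tm_validation")
}

#' @export
print.tm_validation <- function(x, ...) {
  cat("<tm_validation> ", if (x$pass) "PASS" else "FAIL",
      " (tol ", format(x$tol), ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Illustrative Post-Albers transition matrix
#'
#' A strongly cyclic 4-state one-step matrix (E1 -> E1P -> E2P -> E2 -> E1,
#' with small dwell and reverse probabilities). The probabilities are
#' illustrative defaults chosen by this package -- no published per-step
#' probabilities exist for the pump cycle at an arbitrary `dt`.
#'
#' @param dt Nominal time step (arbitrary units).
#' @return A `transition_matrix`.
#' @export
default_post_albers_matrix <- function(dt = 1) {
  P <- matrix(c(
    0.10, 0.80, 0.05, 0.05,
    0.05, 0.10, 0.80, 0.05,
    0.02, 0.08, 0.10, 0.80,
    0.75, 0.05, 0.10, 0.10
  ), nrow = 4, byrow = TRUE)
  transition_matrix(P, state_space(post_albers_states()), dt = dt)
}

#' Evolve a distribution one step
#'
#' Applies the one-step map `x(n+1) = x(n) P` to a probability row vector.
#'
#' @param dist Numeric probability vector over the states (sums to 1).
#' @param P A `transition_matrix` (or plain row-stochastic matrix).
#' @return Numeric probability vector of the same length, named by state.
#' @export
step_distribution <- function(dist, P) {
  P <- as.matrix(P)
  if (length(dist) != nrow(P)) {
    abort("distribution length must match the number of states",
          class = "pumploop_structural_error")
  }
  if (abs(sum(dist) - 1) > 1e-9 || any(dist < -1e-12)) {
    abort("dist must be a probability vector summing to 1",
          class = "pumploop_validation_error")
  }
  out <- as.numeric(dist %*% P)
  names(out) <- rownames(P)
  out
}

# TRUE if every state can reach every other through positive-probability edges
is_strongly_connected <- function(M) {
  g <- igraph::graph_from_adjacency_matrix((as.matrix(M) > 0) * 1, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

# number of closed (recurrent) communicating classes of the positive graph
n_recurrent_classes <- function(M) {
  A <- as.matrix(M) > 0
  g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- 0L
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (!any(A[members, -members, drop = FALSE])) closed <- closed + 1L
  }
  closed
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi = pi P` with `sum(pi) = 1` by power iteration, mirroring the
#' long-run limit of repeated one-step evolution. Iteration runs on the
#' lazily damped matrix `(P + I)/2`, which shares the stationary set of `P`
#' and is aperiodic, so periodic cycles (e.g. deterministic Post-Albers
#' rotation) converge too; the convergence criterion is always evaluated on
#' the undamped `P`.
#'
#' @param P A `transition_matrix` or row-stochastic matrix.
#' @param tol Convergence tolerance on `max|pi P - pi|` (default `1e-10`).
#' @param max_iter Maximum number of damped iterations (default `1e6`).
#' @return A `stationary_distribution` tibble with columns `state`, `pi`,
#'   and attributes `iterations` and `residual`.
#' @export
#' @examples
#' stationary_distribution(default_post_albers_matrix())
stationary_distribution <- function(P, tol = 1e-10, max_iter = 1e6) {
  M <- as.matrix(P)
  if (n_recurrent_classes(M) != 1L) {
    abort("no unique stationary distribution: chain has more than one recurrent class",
          class = "pumploop_validation_error")
  }
  n <- nrow(M)
  D <- (M + diag(n)) / 2
  x <- rep(1 / n, n)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x <- as.numeric(x %*% D)
    x <- x / sum(x)
    res <- max(abs(as.numeric(x %*% M) - x))
    if (res < tol) break
  }
  if (res >= tol) {
    abort(sprintf("power iteration did not converge in %d iterations (residual %.3e)",
                  max_iter, res),
          class = "pumploop_convergence_error")
  }
  states <- tm_states(P)
  new_tibble(
    list(state = unclass(states), pi = x),
    nrow = n,
    class = "stationary_distribution",
    iterations = it,
    residual = res
  )
}

#' @method tidy stationary_distribution
#' @export
tidy.stationary_distribution <- function(x, ...) as_tibble(x)

#' Insert hidden states into a transition matrix
#'
#' Splits selected one-step transitions through new "hidden" intermediate
#' states (e.g. ion-binding sub-states of the Post-Albers conformations)
#' while conserving path probability: the edge `from -> to` with probability
#' `p` becomes `from -> hidden` with probability `p`, then `hidden -> to`
#' with probability `1 - dwell` and `hidden -> hidden` with probability
#' `dwell`, so the total probability of reaching `to` via the hidden state
#' remains `p`. Hidden labels are interleaved directly after their source
#' state.
#'
#' @param P A `transition_matrix`.
#' @param plan Data frame with columns `from`, `to`, `hidden` and optionally
#'   `dwell` (in `[0, 1)`, default 0). One row per edge to split; an empty
#'   or `NULL` plan returns `P` unchanged.
#' @return An expanded `transition_matrix` whose `state_space` marks the new
#'   states as hidden.
#' @export
expand_hidden_states <- function(P, plan = NULL) {
  if (is.null(plan) || nrow(as.data.frame(plan)) == 0) return(P)
  plan <- as_tibble(plan)
  if (!all(c("from", "to", "hidden") %in% names(plan))) {
    abort("plan needs columns from, to, hidden", class = "pumploop_structural_error")
  }
  if (!"dwell" %in% names(plan)) plan$dwell <- 0
  labels <- rownames(as.matrix(P))
  if (!all(plan$from %in% labels) || !all(plan$to %in% labels)) {
    abort("plan refers to unknown states", class = "pumploop_structural_error")
  }
  if (anyDuplicated(plan$hidden) || any(plan$hidden %in% labels)) {
    abort("hidden labels must be new and unique", class = "pumploop_structural_error")
  }
  if (any(plan$dwell < 0 | plan$dwell >= 1)) {
    abort("dwell probabilities must lie in [0, 1)", class = "pumploop_validation_error")
  }
  M <- unclass_matrix(as.matrix(P))
  for (i in seq_len(nrow(plan))) {
    if (M[plan$from[i], plan$to[i]] <= 0) {
      abort(sprintf("edge %s -> %s has zero probability; splitting it breaks conservation",
                    plan$from[i], plan$to[i]),
            class = "pumploop_validation_error")
    }
  }
  # interleave each hidden label right after its source state
  new_labels <- labels
  for (i in seq_len(nrow(plan))) {
    pos <- match(plan$from[i], new_labels)
    new_labels <- append(new_labels, plan$hidden[i], after = pos)
  }
  n <- length(new_labels)
  E <- matrix(0, n, n, dimnames = list(new_labels, new_labels))
  E[labels, labels] <- M
  for (i in seq_len(nrow(plan))) {
    f <- plan$from[i]; t <- plan$to[i]; h <- plan$hidden[i]; d <- plan$dwell[i]
    p <- E[f, t]
    E[f, t] <- 0
    E[f, h] <- p
    E[h, t] <- 1 - d
    E[h, h] <- d
  }
  transition_matrix(E, state_space(new_labels, hidden = plan$hidden),
                    dt = attr(P, "dt") %||% 1)
}

#' Marginal stationary occupancy of visible states
#'
#' Restricts a stationary distribution to the non-hidden states and
#' renormalises, for comparing a hidden-state-expanded chain with its
#' visible core.
#'
#' @param pi A `stationary_distribution`.
#' @param states The `state_space` carrying the hidden markers (defaults to
#'   the one stored on `pi`'s states, if any labels match).
#' @param hidden Character vector of hidden labels (overrides `states`).
#' @return A `stationary_distribution` over the visible states.
#' @export
marginalize_hidden <- function(pi, states = NULL, hidden = NULL) {
  if (is.null(hidden)) {
    hidden <- if (!is.null(states)) attr(states, "hidden") else character()
  }
  keep <- !(pi$state %in% hidden)
  p <- pi$pi[keep] / sum(pi$pi[keep])
  new_tibble(list(state = pi$state[keep], pi = p),
             nrow = sum(keep), class = "stationary_distribution")
}

#' Sample a conformational path
#'
#' Simulates the Markov chain forward from an initial state, returning a
#' seeded, reproducible path of conformations.
#'
#' @param P A `transition_matrix`.
#' @param n_steps Number of transitions to sample (>= 1); the path has
#'   `n_steps + 1` entries including the initial state.
#' @param seed Integer seed for reproducibility.
#' @param init Initial state label (default: first state).
#' @return A tibble with columns `step` (0-based) and `state` (factor with
#'   the state labels as levels, in state-space order).
#' @export
simulate_chain <- function(P, n_steps, seed = 1L, init = NULL) {
  M <- as.matrix(P)
  if (!is.numeric(n_steps) || n_steps < 1) {
    abort("n_steps must be >= 1", class = "pumploop_argument_error")
  }
  n_steps <- as.integer(n_steps)
  labels <- rownames(M)
  init <- init %||% labels[1]
  if (!init %in% labels) abort("unknown initial state", class = "pumploop_argument_error")
  cum <- t(apply(M, 1, cumsum))
  path <- integer(n_steps + 1)
  path[1] <- match(init, labels)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  u <- runif(n_steps)
  for (k in seq_len(n_steps)) {
    path[k + 1] <- which(u[k] <= cum[path[k], ])[1]
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  tibble(
    step = 0:n_steps,
    state = factor(labels[path], levels = labels)
  )
}

#' Empirical state occupancy of a sampled path
#'
#' @param path Tibble from [simulate_chain()].
#' @return Tibble with columns `state`, `n`, `freq`.
#' @export
occupancy <- function(path) {
  tab <- table(path$state)
  tibble(state = names(tab), n = as.integer(tab), freq = as.integer(tab) / nrow(path))
}

#' Read / write transition matrices as CSV
#'
#' CSV layout: header row and first column carry the state labels. Values
#' are written with 17 significant digits so that read-after-write
#' round-trips are exact at double precision.
#'
#' @param P A `transition_matrix`.
#' @param path File path.
#' @param dt Nominal time step attached on read.
#' @return `write_transition_matrix()` returns `path` invisibly;
#'   `read_transition_matrix()` returns a `transition_matrix`.
#' @export
write_transition_matrix <- function(P, path) {
  M <- unclass_matrix(as.matrix(P))
  chr <- matrix(sprintf("%.17g", M), nrow(M), dimnames = dimnames(M))
  write.csv(as.data.frame(chr), path, quote = FALSE, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path, dt = 1) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  transition_matrix(M, state_space(rownames(M)), dt = dt)
}

#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  M <- unclass_matrix(as.matrix(x))
  as_tibble(as.table(M), .name_repair = "minimal") %>%
    setNames(c("from", "to", "p")) %>%
    as_tibble()
}
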