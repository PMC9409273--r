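# Seven-state Markov model of the alpha3beta4 nicotinic receptor channel:
# rate-graph construction, master-equation propagation, stochastic ensemble
# gating and conversion of the open-channel count into a calcium influx.

#' Kinetic parameters of the nAChR gating model
#'
#' Bundles the rate constants of the seven-state nicotinic receptor scheme
#' together with the agonist concentration and the quantities needed to
#' convert gating into calcium influx. Defaults are the values used for
#' bovine chromaffin alpha3beta4 receptors.
#'
#' @param k_plus ACh binding rate constant (uM^-1 s^-1).
#' @param k_minus ACh unbinding rate (s^-1).
#' @param alpha channel closing rate (s^-1).
#' @param beta channel opening rate (s^-1).
#' @param k_pg,k_mg desensitization forward / backward rates (s^-1).
#' @param k_pb forward rate of the slow-inactivation ("b") step. Interpreted
#'   according to the `b_step` argument of [build_rate_graph()]; with the
#'   default `"per_M"` convention its units are M^-1 s^-1 (see Details).
#' @param k_mb backward rate of the slow-inactivation step (s^-1).
#' @param ach_conc agonist (ACh) concentration in uM.
#' @param f_ca fractional contribution of Ca2+ to the single-channel
#'   current (dimensionless, default 0.025, i.e. 2.5%).
#' @param i_unit whole single-channel current amplitude in pA. Not a
#'   published value; 2 pA is an order-of-magnitude default for nAChR at
#'   resting potential and is deliberately configurable.
#'
#' @details
#' The slow-inactivation forward constant is stored as printed (241.5) but is
#' applied by default with a molar concentration convention
#' (`rate = k_pb * ach_conc * 1e-6`, ach in uM). Read literally as
#' uM^-1 s^-1, the b step at 100 uM ACh would run at 24,150 s^-1 against a
#' recovery of 0.3 s^-1, trapping every channel within milliseconds and
#' collapsing a 1-s agonist-evoked current to a sub-millisecond spike --
#' incompatible with the slow seconds-scale inactivation the constant was
#' calibrated to reproduce. See the methods vignette for the full argument;
#' `build_rate_graph(b_step = "per_uM")` restores the literal reading.
#'
#' @return An object of class `channel_params` (a validated list).
#' @seealso [build_rate_graph()], [calcium_influx_rate()]
#' @export
#' @examples
#' p <- channel_params()
#' p$beta / p$alpha   # open/closed equilibrium of the gating step
channel_params <- function(k_plus = 227, k_minus = 38541,
                           alpha = 2024, beta = 50600,
                           k_pg = 49, k_mg = 512,
                           k_pb = 241.5, k_mb = 0.3,
                           ach_conc = 100, f_ca = 0.025, i_unit = 2) {
  p <- list(k_plus = k_plus, k_minus = k_minus, alpha = alpha, beta = beta,
            k_pg = k_pg, k_mg = k_mg, k_pb = k_pb, k_mb = k_mb,
            ach_conc = ach_conc, f_ca = f_ca, i_unit = i_unit)
  rates <- unlist(p[c("k_plus", "k_minus", "alpha", "beta",
                      "k_pg", "k_mg", "k_pb", "k_mb")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(ach_conc) || ach_conc < 0)
    stop("ach_conc must be >= 0")
  if (!is.finite(f_ca) || f_ca < 0 || f_ca > 1)
    stop("f_ca must lie in [0, 1]")
  if (!is.finite(i_unit) || i_unit < 0)
    stop("i_unit must be >= 0")
  structure(p, class = "channel_params")
}

# Rate-expression kinds understood by the graph: a constant (s^-1), a rate
# proportional to [ACh] in uM, and one proportional to [ACh] in M.
.rate_kinds <- c("const", "per_uM_ACh", "per_M_ACh")

#' Construct a general channel-gating rate graph
#'
#' Low-level constructor for a continuous-time Markov gating scheme. Most
#' users will want [build_rate_graph()], which returns the default
#' seven-state nicotinic scheme; this constructor exists so alternative
#' topologies can be supplied as data without code changes.
#'
#' @param states character vector of state names.
#' @param edges data frame with columns `from`, `to` (state names), `kind`
#'   (one of `"const"`, `"per_uM_ACh"`, `"per_M_ACh"`) and `value`
#'   (non-negative rate constant).
#' @param open_state name of the single conducting state.
#' @param ground_state name of the unliganded ground state.
#' @param ach_conc agonist concentration (uM) used to evaluate
#'   ligand-dependent edges.
#' @return An object of class `rate_graph`.
#' @export
rate_graph <- function(states, edges, open_state, ground_state,
                       ach_conc = 100) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state names")
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "kind", "value") %in% names(edges)))
  if (!all(edges$from %in% states) || !all(edges$to %in% states))
    stop("edge endpoints must be named states")
  if (any(edges$from == edges$to)) stop("self-loop edges are not allowed")
  if (!all(edges$kind %in% .rate_kinds))
    stop("edge kind must be one of: ", paste(.rate_kinds, collapse = ", "))
  if (any(!is.finite(edges$value)) || any(edges$value < 0))
    stop("edge rate values must be finite and >= 0")
  if (!open_state %in% states || !ground_state %in% states)
    stop("open_state and ground_state must be named states")
  if (!is.finite(ach_conc) || ach_conc < 0) stop("ach_conc must be >= 0")
  g <- structure(list(states = states,
                      edges = edges[, c("from", "to", "kind", "value")],
                      open_state = open_state,
                      ground_state = ground_state,
                      ach_conc = ach_conc),
                 class = "rate_graph")
  # connectivity check on the undirected skeleton with nonzero potential rate
  n <- length(states)
  if (n > 1) {
    adj <- matrix(FALSE, n, n, dimnames = list(states, states))
    keep <- edges$value > 0
    adj[cbind(edges$from[keep], edges$to[keep])] <- TRUE
    adj <- adj | t(adj)
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen))
      warning("rate graph is not connected (some states are unreachable ",
              "under any agonist concentration)")
  }
  g
}

#' Build the default seven-state nAChR rate graph
#'
#' Linear two-site binding chain `C0 = C1 = C2` (with the standard 2x
#' statistical factors for two equivalent agonist sites), gating `C2 = O`,
#' fast desensitization `O = D = D2`, and slow agonist-dependent
#' inactivation `O = B`. Exactly one state (`O`) conducts.
#'
#' @param params a [channel_params()] object.
#' @param b_step convention for the forward rate of the slow-inactivation
#'   edge `O -> B`: `"per_M"` (default; `k_pb` in M^-1 s^-1, see
#'   [channel_params()] Details), `"per_uM"` (`k_pb` in uM^-1 s^-1,
#'   the literal table reading) or `"const"` (`k_pb` in s^-1, agonist
#'   independent).
#' @param binding_stat_factors logical; apply the 2x statistical factors on
#'   the two-site binding chain (default TRUE).
#' @return A `rate_graph` with states `C0, C1, C2, O, D, D2, B`.
#' @export
#' @examples
#' g <- build_rate_graph(channel_params())
#' rate_generator(g)["C2", "O"]   # the opening rate beta
build_rate_graph <- function(params = channel_params(),
                             b_step = c("per_M", "per_uM", "const"),
                             binding_stat_factors = TRUE) {
  if (!inherits(params, "channel_params")) params <- do.call(channel_params, params)
  b_step <- match.arg(b_step)
  s2 <- if (binding_stat_factors) 2 else 1
  b_kind <- switch(b_step, per_M = "per_M_ACh", per_uM = "per_uM_ACh",
                   const = "const")
  edges <- data.frame(
    from = c("C0", "C1", "C1", "C2", "C2", "O", "O", "D", "D", "D2", "O", "B"),
    to   = c("C1", "C0", "C2", "C1", "O", "C2", "D", "O", "D2", "D", "B", "O"),
    kind = c("per_uM_ACh", "const", "per_uM_ACh", "const", "const", "const",
             "const", "const", "const", "const", b_kind, "const"),
    value = c(s2 * params$k_plus, params$k_minus,
              params$k_plus, s2 * params$k_minus,
              params$beta, params$alpha,
              params$k_pg, params$k_mg,
              params$k_pg, params$k_mg,
              params$k_pb, params$k_mb),
    stringsAsFactors = FALSE
  )
  rate_graph(states = c("C0", "C1", "C2", "O", "D", "D2", "B"),
             edges = edges, open_state = "O", ground_state = "C0",
             ach_conc = params$ach_conc)
}

#' Evaluate the edge rates of a gating graph at its agonist concentration
#'
#' @param graph a `rate_graph`.
#' @return Numeric vector of realized edge rates (s^-1), one per edge.
#' @export
edge_rates <- function(graph) {
  stopifnot(inherits(graph, "rate_graph"))
  e <- graph$edges
  mult <- c(const = 1, per_uM_ACh = graph$ach_conc,
            per_M_ACh = graph$ach_conc * 1e-6)
  unname(e$value * mult[e$kind])
}

#' Generator (transition-rate) matrix of a gating graph
#'
#' @param graph a `rate_graph`.
#' @return Square matrix `Q` with `Q[i, j]` the rate from state i to state j
#'   (s^-1) for `i != j` and rows summing to zero.
#' @export
rate_generator <- function(graph) {
  stopifnot(inherits(graph, "rate_graph"))
  n <- length(graph$states)
  Q <- matrix(0, n, n, dimnames = list(graph$states, graph$states))
  r <- edge_rates(graph)
  for (k in seq_len(nrow(graph$edges)))
    Q[graph$edges$from[k], graph$edges$to[k]] <-
      Q[graph$edges$from[k], graph$edges$to[k]] + r[k]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Occupancy distribution over gating states
#'
#' @param p numeric vector of state occupancies, summing to one.
#' @param graph optional `rate_graph` used to validate names/length.
#' @return Named numeric vector of class `state_distribution`.
#' @export
state_distribution <- function(p, graph = NULL) {
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "rate_graph"))
    if (is.null(names(p))) names(p) <- graph$states
    p <- p[graph$states]
  }
  if (any(!is.finite(p)) || any(p < -1e-12))
    stop("occupancies must be finite and >= 0")
  if (abs(sum(p) - 1) > 1e-9)
    stop("occupancies must sum to 1 (got ", format(sum(p)), ")")
  structure(pmax(p, 0), class = "state_distribution")
}

#' Advance a state distribution by the master equation
#'
#' Propagates `p(t + dt) = p(t) %*% expm(Q dt)` exactly (to matrix-exponential
#' accuracy), serving as the deterministic oracle for the stochastic sampler.
#'
#' @param dist a [state_distribution()] (or bare numeric vector).
#' @param graph a `rate_graph`.
#' @param dt time step in seconds, `dt >= 0`.
#' @return The propagated `state_distribution`.
#' @export
propagate_distribution <- function(dist, graph, dt) {
  stopifnot(inherits(graph, "rate_graph"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt < 0)
    stop("dt must be a single finite number >= 0")
  p <- as.numeric(unclass(dist))
  if (length(p) != length(graph$states))
    stop("distribution length does not match the number of states")
  if (dt == 0) return(state_distribution(stats::setNames(p, graph$states)))
  Q <- rate_generator(graph)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
  out <- as.numeric(p %*% P)
  out <- pmax(out, 0)
  out <- out / sum(out)   # renormalize away residual expm round-off
  state_distribution(stats::setNames(out, graph$states))
}

#' Stationary distribution of a gating graph
#'
#' Computed independently of any time stepping, from the null space of the
#' transposed generator (singular value decomposition).
#'
#' @param graph a `rate_graph`.
#' @return A `state_distribution`.
#' @export
stationary_distribution <- function(graph) {
  Q <- rate_generator(graph)
  s <- svd(t(Q))
  v <- s$v[, ncol(Q)]   # right null vector of Q^T, i.e. pi with pi Q = 0
  v <- abs(v) / sum(abs(v))
  state_distribution(stats::setNames(v, graph$states))
}

#' Sample a stochastic ensemble of gating trajectories
#'
#' Simulates `n_channels` independent channels with fixed-step jump sampling
#' (aggregated per-state multinomial transitions). The requested `dt` is
#' subdivided internally so that the per-substep total exit probability of
#' every state stays below `p_max`.
#'
#' @param n_channels number of channels (>= 0).
#' @param graph a `rate_graph`.
#' @param duration total simulated time (s).
#' @param dt recording time step (s).
#' @param seed optional integer seed (applied via `set.seed`).
#' @param init initial state name or occupancy-count vector; default: all
#'   channels in the graph's ground state.
#' @param p_max maximum per-substep exit probability (default 0.1).
#' @return An `ensemble_trace` list with elements `time` (s), `counts`
#'   (matrix, one column per state), `open_count`, `n_channels`, `seed`.
#' @export
sample_ensemble <- function(n_channels, graph, duration, dt, seed = NULL,
                            init = NULL, p_max = 0.1) {
  stopifnot(inherits(graph, "rate_graph"))
  if (n_channels < 0) stop("n_channels must be >= 0")
  if (duration < 0 || dt <= 0) stop("duration must be >= 0 and dt > 0")
  n_states <- length(graph$states)
  Q <- rate_generator(graph)
  max_exit <- max(-diag(Q))
  n_sub <- max(1L, as.integer(ceiling(max_exit * dt / p_max)))
  if (n_sub > 1e7)
    stop("dt too large: would require more than 1e7 substeps per step")
  counts0 <- integer(n_states)
  if (is.null(init)) {
    counts0[match(graph$ground_state, graph$states)] <- n_channels
  } else if (is.character(init)) {
    counts0[match(init, graph$states)] <- n_channels
  } else {
    stopifnot(length(init) == n_states, sum(init) == n_channels)
    counts0 <- as.integer(init)
  }
  n_steps <- as.integer(round(duration / dt))
  if (!is.null(seed)) set.seed(seed)
  cm <- ensemble_kernel_cpp(counts0, Q, n_steps, n_sub, dt / n_sub)
  colnames(cm) <- graph$states
  open_idx <- match(graph$open_state, graph$states)
  structure(list(time = seq(0, by = dt, length.out = n_steps + 1L),
                 counts = cm,
                 open_count = cm[, open_idx],
                 n_channels = n_channels,
                 seed = seed),
            class = "ensemble_trace")
}

#' Calcium influx carried by a number of open channels
#'
#' Converts an open-channel count into a calcium ion flux, using the
#' fractional calcium current `f_ca` of the unit current and the divalent
#' charge of Ca2+:
#' `ions/s = open_count * f_ca * i_unit / (2 * e)`.
#'
#' @param open_count number of simultaneously open channels (>= 0).
#' @param params a [channel_params()] object.
#' @return Calcium influx in ions per second.
#' @export
#' @examples
#' calcium_influx_rate(1, channel_params(i_unit = 2))  # ~1.56e5 ions/s
calcium_influx_rate <- function(open_count, params = channel_params()) {
  if (!inherits(params, "channel_params")) params <- do.call(channel_params, params)
  if (any(open_count < 0)) stop("open_count must be >= 0")
  open_count * params$f_ca * params$i_unit * 1e-12 / (2 * .const$e_charge)
}

#' Serialize a rate graph to JSON
#'
#' States, edges (with their `"const"` / `"per_uM_ACh"` / `"per_M_ACh"` rate
#' expressions), flags and the agonist concentration are written so that the
#' exact topology is reloadable without code changes.
#'
#' @param graph a `rate_graph`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
rate_graph_to_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "rate_graph"))
  obj <- list(states = graph$states, edges = graph$edges,
              open_state = graph$open_state,
              ground_state = graph$ground_state,
              ach_conc = graph$ach_conc)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a rate graph from JSON
#'
#' @param path file path or a JSON string produced by [rate_graph_to_json()].
#' @return A `rate_graph`.
#' @export
rate_graph_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rate_graph(states = obj$states, edges = as.data.frame(obj$edges),
             open_state = obj$open_state, ground_state = obj$ground_state,
             ach_conc = obj$ach_conc)
}

#' Export an ensemble trace as CSV
#'
#' Columns: `time_s`, one count column per state, `open_count`.
#'
#' @param trace an `ensemble_trace` from [sample_ensemble()].
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_ensemble_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ensemble_trace"))
  df <- data.frame(time_s = trace$time, trace$counts,
                   open_count = trace$open_count, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.rate_graph <- function(x, ...) {
  cat("<rate_graph> ", length(x$states), " states: ",
      paste(x$states, collapse = ", "), "\n",
      "  open: ", x$open_state, "; ground: ", x$ground_state,
      "; [ACh] = ", x$ach_conc, " uM; ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @export
print.ensemble_trace <- function(x, ...) {
  cat("<ensemble_trace> ", x$n_channels, " channels, ",
      length(x$time), " time points over ",
      format(max(x$time)), " s\n", sep = "")
  invisible(x)
}
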