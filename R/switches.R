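#' Define a micro-switch distance metric
#'
#' A micro-switch is a named interatomic distance with a classification
#' threshold: the switch is "engaged" in a frame when the distance is on
#' the stated side of the threshold.  The boundary is inclusive — a
#' distance exactly equal to the threshold counts as engaged when
#' `engaged_when = "le_threshold"` (the activation criterion is
#' "equal or lower than" the cutoff).
#'
#' @param name switch label used in outputs.
#' @param sel_a,sel_b atom selectors: `list(bw = "6.44", role = "ring_C4")`.
#' @param threshold_A distance threshold in Angstrom, or `NA` for an
#'   unclassified reporter distance.
#' @param engaged_when `"le_threshold"` (engaged iff distance <= threshold)
#'   or `"gt_threshold"`.
#' @param pair_reduction `"single_pair"` or `"min_over_pairs"` (per-frame
#'   minimum over the cross product of the two atom sets, used for
#'   salt-bridge criteria).
#' @return A list of class `switch_definition`.
#' @export
switch_definition <- function(name, sel_a, sel_b, threshold_A = NA_real_,
                              engaged_when = c("le_threshold", "gt_threshold"),
                              pair_reduction = c("single_pair",
                                                 "min_over_pairs")) {
  engaged_when <- match.arg(engaged_when)
  pair_reduction <- match.arg(pair_reduction)
  if (!is.na(threshold_A) && threshold_A <= 0) {
    abort("switch threshold must be positive")
  }
  structure(list(name = name, sel_a = sel_a, sel_b = sel_b,
                 threshold_A = threshold_A, engaged_when = engaged_when,
                 pair_reduction = pair_reduction),
            class = "switch_definition")
}

#' Built-in micro-switch definitions
#'
#' The standard monitoring set for an aminergic receptor:
#' \describe{
#'   \item{F6.44 activation}{ring C-4 (CZ) of F6.44 to the C-alpha of 5.50,
#'     engaged (active) at <= 9.5 Angstrom.}
#'   \item{F6.41 activation}{ring C-4 of F6.41 to the C-alpha of 5.54,
#'     engaged at <= 9.5 Angstrom.}
#'   \item{ionic lock}{C-epsilon of R3.50 to C-delta of E6.30, closed at
#'     <= 5 Angstrom.}
#'   \item{D3.49-R3.50 salt bridge}{minimum over Asp carboxylate oxygens x
#'     Arg guanidinium nitrogens, formed at <= `salt_bridge_cutoff_A`
#'     (default 4, the standard salt-bridge criterion).}
#'   \item{Y7.53 reporters}{OH of Y7.53 to the C-alpha of 3.50 and of 2.40;
#'     raw distances, never binarised.}
#' }
#'
#' @param receptor optional receptor label (carried into outputs only).
#' @param salt_bridge_cutoff_A configurable D3.49-R3.50 criterion.
#' @return Named list of [switch_definition()] objects.
#' @export
builtin_switch_definitions <- function(receptor = NA_character_,
                                       salt_bridge_cutoff_A = 4.0) {
  defs <- list(
    switch_definition("F6.44 activation",
                      list(bw = "6.44", role = "ring_C4"),
                      list(bw = "5.50", role = "CA"), 9.5),
    switch_definition("F6.41 activation",
                      list(bw = "6.41", role = "ring_C4"),
                      list(bw = "5.54", role = "CA"), 9.5),
    switch_definition("Ionic lock closure",
                      list(bw = "3.50", role = "arg_CE"),
                      list(bw = "6.30", role = "glu_CD"), 5.0),
    switch_definition("D3.49-R3.50 salt bridge",
                      list(bw = "3.49", role = "carboxylate_O_pair"),
                      list(bw = "3.50", role = "guanidinium_N_set"),
                      salt_bridge_cutoff_A,
                      pair_reduction = "min_over_pairs"),
    switch_definition("Y7.53-H3 distance",
                      list(bw = "7.53", role = "tyr_OH"),
                      list(bw = "3.50", role = "CA")),
    switch_definition("Y7.53-H2 distance",
                      list(bw = "7.53", role = "tyr_OH"),
                      list(bw = "2.40", role = "CA"))
  )
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Per-frame interatomic distance series
#'
#' Plain Euclidean distances (intramolecular distances never span the
#' periodic box in wrapped trajectories, so no minimum-image convention is
#' applied by default).  With multi-atom selections the per-frame minimum
#' over all A x B pairs is returned when `reduction = "min_over_pairs"`.
#'
#' @param traj an [md_trajectory()].
#' @param idx_a,idx_b atom index vectors.
#' @param reduction `"single_pair"` (both selections length 1) or
#'   `"min_over_pairs"`.
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
distance_series <- function(traj, idx_a, idx_b,
                            reduction = c("single_pair", "min_over_pairs")) {
  reduction <- match.arg(reduction)
  na <- n_atoms(traj)
  stopifnot(all(idx_a >= 1 & idx_a <= na), all(idx_b >= 1 & idx_b <= na))
  pair_dist <- function(a, b) {
    d <- traj$coords[, a, , drop = FALSE] - traj$coords[, b, , drop = FALSE]
    sqrt(rowSums(matrix(d, nrow = dim(d)[1])^2))
  }
  if (reduction == "single_pair") {
    if (length(idx_a) != 1L || length(idx_b) != 1L) {
      abort("single_pair reduction requires one atom per selection")
    }
    return(pair_dist(idx_a, idx_b))
  }
  out <- rep(Inf, n_frames(traj))
  for (a in idx_a) for (b in idx_b) out <- pmin(out, pair_dist(a, b))
  out
}

#' Classify distances into engaged / disengaged states
#'
#' @param distances numeric vector of distances (Angstrom).
#' @param definition a [switch_definition()]; its threshold and
#'   `engaged_when` side define the rule.  The boundary is inclusive:
#'   `distance == threshold` is engaged under `le_threshold`.
#' @return Logical vector (`NA` throughout for unclassified reporters).
#' @export
classify_states <- function(distances, definition) {
  stopifnot(inherits(definition, "switch_definition"))
  if (is.na(definition$threshold_A)) {
    return(rep(NA, length(distances)))
  }
  if (definition$engaged_when == "le_threshold") {
    distances <= definition$threshold_A
  } else {
    distances > definition$threshold_A
  }
}

#' Compute a tidy switch series for one trajectory
#'
#' Resolves the definition's selectors against the topology, measures the
#' per-frame distance and classifies it.
#'
#' @param traj an [md_trajectory()].
#' @param top a [topology_map()].
#' @param definition a [switch_definition()].
#' @return A tibble of class `switch_series`: `switch`, `replicate`,
#'   `time_ps`, `distance_A`, `engaged`.
#' @export
switch_series <- function(traj, top, definition) {
  stopifnot(inherits(definition, "switch_definition"))
  idx_a <- select_atom(top, definition$sel_a$bw, definition$sel_a$role)
  idx_b <- select_atom(top, definition$sel_b$bw, definition$sel_b$role)
  d <- distance_series(traj, idx_a, idx_b,
                       reduction = definition$pair_reduction)
  out <- tibble(switch = definition$name,
                replicate = traj$replicate,
                time_ps = traj$times,
                distance_A = d,
                engaged = classify_states(d, definition))
  class(out) <- c("switch_series", class(out))
  attr(out, "definition") <- definition
  out
}

#' Engagement statistics across replicates
#'
#' Per-replicate and pooled engagement percentages for each switch.  The
#' pooled figure is frame-weighted over the concatenated replicates
#' (`100 * sum(engaged) / sum(frames)`), not a mean of replicate means, so
#' replicates of unequal length are weighted by their frame counts — the
#' convention for a percentage quoted "over total simulation time".
#'
#' @param series a `switch_series` tibble, or several row-bound together
#'   (multiple switches and replicates allowed).
#' @return An object of class `engagement_summary`; see [tidy()] for the
#'   per-replicate table and [glance()] for the pooled one.
#' @export
engagement_summary <- function(series) {
  stopifnot(is.data.frame(series), nrow(series) > 0)
  if (all(is.na(series$engaged))) {
    abort("no classified switch states to summarise")
  }
  per_rep <- series %>%
    filter(!is.na(.data$engaged)) %>%
    group_by(.data$switch, .data$replicate) %>%
    summarise(n_frames = n(),
              n_engaged = sum(.data$engaged),
              pct_engaged = 100 * mean(.data$engaged),
              .groups = "drop")
  pooled <- per_rep %>%
    group_by(.data$switch) %>%
    summarise(n_replicates = n(),
              n_frames = sum(.data$n_frames),
              n_engaged = sum(.data$n_engaged),
              pct_engaged = 100 * sum(.data$n_engaged) / sum(.data$n_frames),
              .groups = "drop")
  structure(list(per_replicate = per_rep, pooled = pooled),
            class = "engagement_summary")
}

#' @export
print.engagement_summary <- function(x, ...) {
  cat("Engagement summary (pooled over replicates, frame-weighted):\n")
  print(x$pooled)
  invisible(x)
}

#' @rdname engagement_summary
#' @param x an `engagement_summary`.
#' @param ... unused.
#' @export
tidy.engagement_summary <- function(x, ...) x$per_replicate

#' @rdname engagement_summary
#' @export
glance.engagement_summary <- function(x, ...) x$pooled

#' Count state transitions in a binary state series
#'
#' Number of consecutive-frame changes between engaged and disengaged.
#'
#' @param states logical vector.
#' @return Integer count; series shorter than 2 frames give 0 with a
#'   warning.
#' @export
transition_count <- function(states) {
  states <- states[!is.na(states)]
  if (length(states) < 2L) {
    warn("fewer than 2 classified frames; transition count is 0")
    return(0L)
  }
  sum(states[-1] != states[-length(states)])
}

#' Autocorrelation-adjusted confidence interval for an engagement fraction
#'
#' Binary state series from MD are serially correlated, so the binomial
#' variance `p(1-p)/n` understates the uncertainty.  The lag-1
#' autocorrelation `rho` of the state indicator gives an effective sample
#' size `n_eff = n (1-rho)/(1+rho)` (the standard Markov-chain correction),
#' and a normal-approximation interval is built on that.
#'
#' @param states logical vector of engaged flags.
#' @param level confidence level (default 0.99).
#' @return A tibble: `p_hat`, `n`, `n_eff`, `rho`, `lower`, `upper`.
#' @export
engagement_ci <- function(states, level = 0.99) {
  states <- as.numeric(states[!is.na(states)])
  n <- length(states)
  stopifnot(n >= 2)
  p_hat <- mean(states)
  rho <- if (sd(states) == 0) 0 else {
    stats::cor(states[-1], states[-n])
  }
  rho <- max(min(rho, 0.999), 0)
  n_eff <- max(n * (1 - rho) / (1 + rho), 2)
  se <- sqrt(max(p_hat * (1 - p_hat), 1e-12) / n_eff)
  z <- qnorm(1 - (1 - level) / 2)
  tibble(p_hat = p_hat, n = n, n_eff = n_eff, rho = rho,
         lower = max(0, p_hat - z * se), upper = min(1, p_hat + z * se))
}
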