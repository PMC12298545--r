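# Hierarchical multi-objective reward: validity, degradability
# sub-rewards (enzyme, hydrolysis, microplastic, kinetics),
# properties, synthesis, plus the Tanimoto diversity bonus and
# first-order meta-learning of the reward weights.

#' Hierarchical reward weights
#'
#' `alpha`, `beta`, `gamma` weight the degradability, property and
#' synthesis branches of the total reward; `w1..w4` weight the
#' degradability sub-rewards (enzyme, hydrolysis, microplastic,
#' kinetics). The microplastic and kinetics terms rest on package
#' placeholders, so their weights default to 0 and results never
#' silently depend on them.
#'
#' @param alpha,beta,gamma Hierarchical weights (non-negative).
#' @param w1,w2,w3,w4 Degradability component weights (non-negative).
#' @return A `reward_weights`.
#' @export
reward_weights <- function(alpha = 1, beta = 1, gamma = 1,
                           w1 = 0.5, w2 = 0.5, w3 = 0, w4 = 0) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma,
         w1 = w1, w2 = w2, w3 = w3, w4 = w4)
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(as.list(w), class = "reward_weights")
}

#' Validity reward
#'
#' Immediate feedback on chemical validity: 1.0 when the action
#' maintains validity, -10.0 otherwise.
#'
#' @param report A `validity_report` from [check_validity()].
#' @return 1.0 or -10.0.
#' @export
validity_reward <- function(report) {
  if (isTRUE(report$valid)) 1.0 else -10.0
}

# Surface-derived binding features shared by the surrogate provider:
# ester SASA fraction and hydrophobic (carbon) contact score. The
# conformer / per-atom areas can be passed in to avoid recomputation.
binding_features <- function(graph, conf = embed_conformer(graph),
                             areas = shrake_rupley_sasa(conf)) {
  total <- sum(areas)
  esters <- find_ester_groups(graph)
  list(
    ester_frac = if (total > 0 && length(esters$atoms)) sum(areas[esters$atoms]) / total else 0,
    hydrophobic = if (total > 0) sum(areas[graph$nodes$element == "C"]) / total else 0
  )
}

#' Deterministic surrogate binding-energy provider
#'
#' Maps a polymer graph to one binding free energy per enzyme:
#' `dG_bind_e = -(a_e * ester-SASA-fraction + b_e * hydrophobic-contact)`
#' (kJ/mol-like scale, more negative = stronger binding). Stands in
#' for docking; any function with the same signature can replace it
#' in an [enzyme_panel()].
#'
#' @param graph A `poly_graph`.
#' @param enzymes Tibble with per-enzyme columns `a` and `b`.
#' @return Numeric vector of binding energies, one per enzyme.
#' @export
surrogate_binding_provider <- function(graph, enzymes) {
  f <- attr(graph, "binding_features") %||% binding_features(graph)
  -(enzymes$a * f$ester_frac + enzymes$b * f$hydrophobic)
}

#' Enzyme panel
#'
#' @param enzymes Tibble `enzyme_id, mu, sigma, a, b` (all `sigma`
#'   strictly positive; `a`, `b` feed the default surrogate).
#' @param provider Binding-energy provider,
#'   `function(graph, enzymes) -> numeric`.
#' @return An `enzyme_panel`.
#' @export
enzyme_panel <- function(enzymes, provider = surrogate_binding_provider) {
  stopifnot(all(c("enzyme_id", "mu", "sigma") %in% names(enzymes)),
            all(enzymes$sigma > 0))
  structure(list(enzymes = tibble::as_tibble(enzymes), provider = provider),
            class = "enzyme_panel")
}

#' Read / write an enzyme panel as CSV (`enzyme_id,mu,sigma,a,b`)
#'
#' @param path File path.
#' @return `read_enzyme_panel()` returns an `enzyme_panel` backed by
#'   the surrogate provider.
#' @export
read_enzyme_panel <- function(path) {
  enzyme_panel(tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)))
}

#' @rdname read_enzyme_panel
#' @param panel An `enzyme_panel`.
#' @export
write_enzyme_panel <- function(panel, path) {
  utils::write.csv(panel$enzymes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enzyme-susceptibility reward
#'
#' Mean over the panel of `sigmoid((-dG_bind_e - mu_e) / sigma_e)`:
#' binding stronger than the enzyme's calibration midpoint pushes the
#' term toward 1. Enzymes whose provider call fails are skipped with
#' a warning; if every enzyme fails, scoring fails.
#'
#' @param graph A `poly_graph`.
#' @param panel An [enzyme_panel()].
#' @return Value in (0, 1).
#' @export
enzyme_reward <- function(graph, panel) {
  stopifnot(nrow(panel$enzymes) > 0)
  dg <- tryCatch(panel$provider(graph, panel$enzymes), error = function(e) {
    warning("binding provider failed for the whole panel: ", conditionMessage(e))
    rep(NA_real_, nrow(panel$enzymes))
  })
  x <- (-dg - panel$enzymes$mu) / panel$enzymes$sigma
  ok <- is.finite(x)
  if (!any(ok)) stop("no enzyme could be scored", call. = FALSE)
  if (any(!ok)) warning(sum(!ok), " enzyme(s) skipped in enzyme_reward")
  mean(sigmoid(x[ok]))
}

#' Hydrolysis-susceptibility reward
#'
#' `rho_ester * SASA_ester / SASA_total`: ester-bond density (ester
#' bonds per heavy atom of the repeat unit) scaled by the surface
#' fraction belonging to ester-group atoms, so buried esters count
#' less than exposed ones.
#'
#' @param graph A `poly_graph`.
#' @param conf Matching [conformer()] (defaults to the embedded one).
#' @param areas Optional precomputed per-atom SASA for `conf`.
#' @return Non-negative value, at most the ester density.
#' @export
hydrolysis_reward <- function(graph, conf = embed_conformer(graph),
                              areas = NULL) {
  n <- nrow(graph$nodes)
  if (n == 0) return(0)
  if (nrow(conf$coords) != n) {
    stop("conformer does not align with graph nodes", call. = FALSE)
  }
  esters <- find_ester_groups(graph)
  if (nrow(esters$bonds) == 0) return(0)
  if (is.null(areas)) areas <- shrake_rupley_sasa(conf)
  total <- sum(areas)
  if (total <= 0) stop("degenerate geometry: zero total SASA", call. = FALSE)
  rho <- nrow(esters$bonds) / n
  rho * sum(areas[esters$atoms]) / total
}

#' Microplastic-resistance placeholder reward
#'
#' Fragment-size penalty proxy: larger repeat structures that shed
#' smaller counts of persistent fragments score higher. A documented
#' placeholder (weighted 0 by default).
#'
#' @param graph A `poly_graph`.
#' @return Value in (0, 1].
#' @export
microplastic_reward <- function(graph) {
  exp(-nrow(graph$nodes) / 50)
}

#' Degradation-kinetics placeholder reward
#'
#' One minus the absolute deviation of a first-order rate proxy (the
#' ester density) from a target rate, floored at 0. A documented
#' placeholder (weighted 0 by default).
#'
#' @param graph A `poly_graph`.
#' @param target Target rate proxy (default 0.1 esters per heavy
#'   atom).
#' @return Value in \[0, 1\].
#' @export
kinetics_reward <- function(graph, target = 0.1) {
  n <- nrow(graph$nodes)
  rho <- if (n > 0) nrow(find_ester_groups(graph)$bonds) / n else 0
  max(0, 1 - abs(rho - target))
}

#' Degradability reward (weighted sum of sub-rewards)
#'
#' `w1 * r_enzyme + w2 * r_hydrolysis + w3 * r_microplastic +
#' w4 * r_kinetics`.
#'
#' @param parts Named list with `r_enzyme`, `r_hydrolysis`,
#'   `r_microplastic`, `r_kinetics`.
#' @param w A [reward_weights()].
#' @return Scalar.
#' @export
degradability_reward <- function(parts, w = reward_weights()) {
  need <- c("r_enzyme", "r_hydrolysis", "r_microplastic", "r_kinetics")
  stopifnot(all(need %in% names(parts)))
  w$w1 * parts$r_enzyme + w$w2 * parts$r_hydrolysis +
    w$w3 * parts$r_microplastic + w$w4 * parts$r_kinetics
}

#' Total hierarchical reward
#'
#' `r_total = r_validity + alpha * r_degradability + beta *
#' r_properties + gamma * r_synthesis`. The degradability branch is
#' recomputed from its four sub-rewards; the diversity bonus is
#' carried alongside (logged, and added to the per-step training
#' reward with its own coefficient) rather than folded into the
#' hierarchical sum.
#'
#' @param parts Named list with `r_validity`, the four degradability
#'   sub-rewards, and optionally `r_properties`, `r_synthesis`,
#'   `r_diversity` (default 0).
#' @param w A [reward_weights()].
#' @return A `reward_breakdown` (also a tibble row via
#'   [as_tibble_breakdown()]).
#' @export
total_reward <- function(parts, w = reward_weights()) {
  r_prop <- parts$r_properties %||% 0
  r_syn <- parts$r_synthesis %||% 0
  r_div <- parts$r_diversity %||% 0
  r_deg <- degradability_reward(parts, w)
  structure(
    list(
      r_validity = parts$r_validity,
      r_enzyme = parts$r_enzyme, r_hydrolysis = parts$r_hydrolysis,
      r_microplastic = parts$r_microplastic, r_kinetics = parts$r_kinetics,
      r_degradability = r_deg,
      r_properties = r_prop, r_synthesis = r_syn, r_diversity = r_div,
      r_total = parts$r_validity + w$alpha * r_deg + w$beta * r_prop +
        w$gamma * r_syn
    ),
    class = "reward_breakdown"
  )
}

#' Reward breakdown as a one-row tibble
#'
#' @param x A `reward_breakdown`.
#' @return One-row tibble with every component column.
#' @export
as_tibble_breakdown <- function(x) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat("<reward_breakdown> total ", format(x$r_total, digits = 4),
      " (validity ", x$r_validity, ", degradability ",
      format(x$r_degradability, digits = 4), ")\n", sep = "")
  invisible(x)
}

# --- diversity ---------------------------------------------------------------

#' Bounded FIFO buffer of generated-polymer fingerprints
#'
#' @param capacity Maximum number of retained fingerprints.
#' @return A `diversity_buffer` (environment-backed, mutated in
#'   place by [push_fingerprint()]).
#' @export
diversity_buffer <- function(capacity = 256L) {
  e <- new.env(parent = emptyenv())
  e$fps <- list()
  e$capacity <- as.integer(capacity)
  class(e) <- "diversity_buffer"
  e
}

#' @rdname diversity_buffer
#' @param buffer A `diversity_buffer`.
#' @param fp A `fingerprint` to append (oldest entry dropped at
#'   capacity).
#' @export
push_fingerprint <- function(buffer, fp) {
  buffer$fps[[length(buffer$fps) + 1L]] <- fp
  if (length(buffer$fps) > buffer$capacity) buffer$fps <- buffer$fps[-1L]
  invisible(buffer)
}

#' Diversity reward against previously generated polymers
#'
#' Minimum Tanimoto distance between `fp` and every fingerprint in
#' the buffer; an empty buffer scores 1 (a first structure is
#' maximally novel by convention).
#'
#' @param fp A `fingerprint`.
#' @param buffer A [diversity_buffer()].
#' @return Value in \[0, 1\].
#' @export
diversity_reward <- function(fp, buffer) {
  if (length(buffer$fps) == 0) return(1)
  min(vapply(buffer$fps, function(b) tanimoto_distance(fp, b), numeric(1)))
}

# --- meta-learning of reward weights ----------------------------------------

#' First-order meta-update of the reward weights
#'
#' Treats the reward weights as the outer variable of a bi-level
#' problem: for each validation task, the task's inner routine is run
#' for `inner_steps` with the current weights and returns a
#' validation loss; the outer gradient is estimated by forward finite
#' differences on each weight and a gradient step is taken, clipping
#' the weights at zero. Tasks with non-finite losses are skipped with
#' a warning.
#'
#' @param w A [reward_weights()].
#' @param tasks List of functions `function(w, inner_steps) ->
#'   validation loss`.
#' @param inner_steps Inner training steps per task (>= 1).
#' @param meta_rate Outer learning rate (0 leaves weights unchanged).
#' @param h Finite-difference step (default 1e-3).
#' @return Updated `reward_weights`.
#' @export
meta_update_weights <- function(w, tasks, inner_steps = 1L, meta_rate = 0.05,
                                h = 1e-3) {
  stopifnot(length(tasks) >= 1, inner_steps >= 1)
  if (meta_rate == 0) return(w)
  wv <- unlist(w, use.names = TRUE)
  task_loss <- function(wv) {
    wl <- do.call(reward_weights, as.list(wv))
    sum(vapply(tasks, function(tk) tk(wl, inner_steps), numeric(1)))
  }
  base <- task_loss(wv)
  if (!is.finite(base)) {
    warning("non-finite validation loss; meta-update skipped")
    return(w)
  }
  grad <- numeric(length(wv))
  for (i in seq_along(wv)) {
    wp <- wv
    wp[i] <- wp[i] + h
    li <- task_loss(wp)
    grad[i] <- if (is.finite(li)) (li - base) / h else 0
  }
  out <- pmax(0, wv - meta_rate * grad)
  do.call(reward_weights, as.list(out))
}
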