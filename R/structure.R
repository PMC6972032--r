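#' Define a multi-state transition structure
#'
#' A structure names the states, marks the absorbing ones, and lists the
#' directed transitions that may occur instantaneously.  Observed panel
#' pairs outside this set are still allowed in the likelihood (they occur
#' via intermediate jumps); disallowed entries of the generator are
#' structural zeros, never estimated.
#'
#' @param states character vector of state codes, in order.
#' @param transitions character vector of transitions, each `"X->Y"`
#'   (whitespace ignored), or a two-column matrix of from/to codes.
#' @param absorbing character vector of absorbing state codes.
#' @param labels optional named character vector of long state labels.
#' @return an object of class `msm_structure` with elements `states`,
#'   `labels`, `absorbing`, `from`, `to` (integer state indices),
#'   `trans` (transition labels) and `n_states`/`n_trans`.
#' @examples
#' msm_structure(c("alive", "dead"), "alive->dead", absorbing = "dead")
#' @export
msm_structure <- function(states, transitions, absorbing, labels = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state codes")
  if (is.character(transitions)) {
    parts <- strsplit(gsub("[[:space:]]", "", transitions), "->", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed transition(s): ", paste(transitions[bad], collapse = ", "))
    tmat <- do.call(rbind, parts)
  } else {
    tmat <- as.matrix(transitions)
    if (ncol(tmat) != 2L) stop("'transitions' matrix must have two columns")
  }
  from <- match(tmat[, 1L], states)
  to <- match(tmat[, 2L], states)
  if (anyNA(from) || anyNA(to)) stop("transition references unknown state")
  if (any(from == to)) stop("self-transitions are not allowed")
  if (anyDuplicated(cbind(from, to))) stop("duplicate transitions")
  absorbing <- as.character(absorbing)
  if (!all(absorbing %in% states)) stop("absorbing state not among states")
  if (any(states[from] %in% absorbing)) {
    stop("absorbing states cannot have outgoing transitions")
  }
  live <- setdiff(states, absorbing)
  no_exit <- setdiff(live, states[from])
  if (length(no_exit)) {
    stop("non-absorbing state(s) with no outgoing transition: ",
         paste(no_exit, collapse = ", "))
  }
  if (is.null(labels)) labels <- setNames(states, states)
  structure(
    list(states = states, labels = labels, absorbing = absorbing,
         from = as.integer(from), to = as.integer(to),
         trans = paste0(states[from], "->", states[to]),
         n_states = length(states), n_trans = length(from)),
    class = "msm_structure"
  )
}

#' The five-state hip osteoarthritis model
#'
#' States: A = no radiographic hip OA (rHOA) and no symptoms, B =
#' asymptomatic rHOA, C = hip symptoms only, D = symptomatic hip OA
#' (rHOA plus symptoms in the same hip), E = death (absorbing).  Ten
#' transitions are allowed: development of rHOA (A->B, C->D), development
#' of symptoms (A->C, B->D), resolution of symptoms (C->A, D->B), and
#' death from any living state.  The diagonal moves A->D and C->B are
#' excluded as instantaneous transitions; observed A/D or C/B panel pairs
#' are explained by two jumps through an intermediate state.
#'
#' @return an [msm_structure] object.
#' @export
hip_structure <- function() {
  msm_structure(
    states = c("A", "B", "C", "D", "E"),
    labels = c(A = "No rHOA/symptoms", B = "Asymptomatic rHOA",
               C = "Symptoms only", D = "Symptomatic HOA", E = "Death"),
    transitions = c("A->B", "A->C", "C->A", "C->D", "B->D", "D->B",
                    "A->E", "B->E", "C->E", "D->E"),
    absorbing = "E"
  )
}

#' The six living-state transitions reported in results tables
#'
#' Transitions into death are modeled but suppressed from default reports.
#' Order follows the conventional grouping: development of rHOA, development
#' of symptoms, resolution of symptoms.
#' @return character vector of transition labels.
#' @export
reported_transitions <- function() {
  c("A->B", "C->D", "A->C", "B->D", "C->A", "D->B")
}

#' @export
print.msm_structure <- function(x, ...) {
  cat("Multi-state structure:", x$n_states, "states,", x$n_trans, "transitions\n")
  cat("  states   :", paste(x$states, collapse = " "),
      " (absorbing:", paste(x$absorbing, collapse = " "), ")\n")
  cat("  allowed  :", paste(x$trans, collapse = ", "), "\n")
  invisible(x)
}

#' Specify model covariates
#'
#' Covariates act multiplicatively on transition intensities
#' (log-linear model); the reference level of each covariate must be coded
#' as 0 so the baseline intensities retain their interpretation.
#'
#' @param names character vector of covariate (column) names.
#' @param kind per-covariate kind, `"static"` or `"time-dependent"`;
#'   recycled.
#' @param mask transition inclusion: `"all"` (every transition),
#'   `"living"` (transitions between living states only), or a logical
#'   `n_trans x K` matrix.
#' @param structure the [msm_structure] the mask refers to.
#' @return object of class `msm_covariates`.
#' @export
msm_covariates <- function(names, kind = "time-dependent", mask = "all",
                           structure = hip_structure()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("duplicate covariate names")
  K <- length(names)
  kind <- rep_len(match.arg(kind, c("static", "time-dependent"), several.ok = TRUE),
                  K)
  if (is.character(mask)) {
    mask <- match.arg(mask, c("all", "living"))
    m <- matrix(TRUE, structure$n_trans, K)
    if (mask == "living") {
      into_abs <- structure$states[structure$to] %in% structure$absorbing
      m[into_abs, ] <- FALSE
    }
    mask <- m
  }
  mask <- as.matrix(mask)
  if (K == 0L) mask <- matrix(logical(), structure$n_trans, 0L)
  if (nrow(mask) != structure$n_trans || ncol(mask) != K) {
    stop("mask must be n_trans x K")
  }
  dimnames(mask) <- list(structure$trans, names)
  structure(list(names = names, kind = setNames(kind, names), K = K,
                 mask = mask),
            class = "msm_covariates")
}

#' Read a declarative model configuration
#'
#' The configuration is a YAML file with keys `states`, `absorbing`,
#' `transitions` (each `"X->Y"`), optional `labels`, and optional
#' `covariates` (list with `names`, `kind`, `mask`).  The packaged default
#' (`system.file("extdata", "hip_model.yaml", package = "hipmsm")`) encodes
#' the five-state hip OA structure.
#'
#' @param path file path.
#' @return list with elements `structure` and (if given) `covariates`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("states", "transitions", "absorbing")) {
    if (is.null(cfg[[key]])) stop("config missing key '", key, "'")
  }
  labels <- if (!is.null(cfg$labels)) unlist(cfg$labels) else NULL
  st <- msm_structure(cfg$states, unlist(cfg$transitions), cfg$absorbing,
                      labels = labels)
  out <- list(structure = st)
  if (!is.null(cfg$covariates)) {
    cv <- cfg$covariates
    mask <- if (is.null(cv$mask)) "all" else cv$mask
    if (is.list(mask)) mask <- do.call(rbind, lapply(mask, as.logical))
    out$covariates <- msm_covariates(unlist(cv$names),
                                     kind = if (is.null(cv$kind)) "time-dependent" else unlist(cv$kind),
                                     mask = mask, structure = st)
  }
  out
}

# States reachable from each state through allowed transitions (reflexive
# transitive closure); used to detect structurally impossible panel pairs.
reachable_states <- function(structure) {
  n <- structure$n_states
  adj <- diag(n) > 0
  adj[cbind(structure$from, structure$to)] <- TRUE
  for (k in seq_len(n)) adj <- adj | (adj %*% adj) > 0
  dimnames(adj) <- list(structure$states, structure$states)
  adj
}
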