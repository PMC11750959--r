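#' Create a measured flux constraint
#'
#' A constraint pins the flux of one reaction to a measured value (an
#' accumulation or consumption rate derived from concentration time
#' series), either exactly (`tolerance = 0`) or within a band of half-width
#' `tolerance`. All values are in mmol/gDW/day.
#'
#' @param reaction_id reaction the measurement maps to.
#' @param value measured flux value.
#' @param tolerance band half-width; 0 means strict equality.
#' @param day,condition snapshot labels.
#' @return one-row data.frame with columns `reaction_id`, `kind`, `value`,
#'   `tolerance`, `day`, `condition`.
#' @export
flux_constraint <- function(reaction_id, value, tolerance = 0,
                            day = NA_integer_, condition = NA_character_) {
  stopifnot(is.finite(value), tolerance >= 0)
  data.frame(reaction_id = reaction_id,
             kind = if (tolerance > 0) "band" else "equality",
             value = value, tolerance = tolerance,
             day = day, condition = condition,
             stringsAsFactors = FALSE)
}

#' Solve one daily flux snapshot by quadratic programming
#'
#' Finds the flux vector `v` minimising the quadratic norm
#' `sum(w * v^2)` subject to steady state for internal metabolites
#' (`S_int %*% v = 0`), the reaction bounds, and the measured constraints.
#' The unweighted quadratic norm (all `w = 1`) is the default objective;
#' because it is strictly convex the flux distribution is unique.
#'
#' If the strict measured constraints are jointly infeasible, a two-stage
#' relaxation is applied: first the sum of squared constraint violations is
#' minimised over the steady-state polytope, then the flux norm is
#' minimised at that fixed minimal violation. The result carries
#' `status = "relaxed"` with per-constraint residuals. If even the
#' steady-state system conflicts with the bounds, `status = "infeasible"`
#' is returned with a diagnostic naming the most violated metabolite
#' balances and the reactions pinned at their bounds.
#'
#' @param network a [reaction_network()].
#' @param constraints data.frame of measured constraints (see
#'   [flux_constraint()]); all rows must share one `(day, condition)`.
#' @param options list; `weights` (per-reaction objective weights, named or
#'   in declaration order), `tol` (solver feasibility tolerance, default
#'   1e-9), `relative_band` (global relative tolerance turning equality
#'   constraints into bands, default 0).
#' @return object of class `flux_solution`: `fluxes` (named vector),
#'   `day`, `condition`, `objective_value` (sum of squared fluxes),
#'   `max_steady_state_residual`, `constraint_residuals` (violation beyond
#'   tolerance per constraint), `status` ("optimal", "relaxed" or
#'   "infeasible"), `diagnostic`.
#' @export
solve_snapshot_fluxes <- function(network, constraints, options = list()) {
  tol <- options$tol %||% 1e-9
  rel <- options$relative_band %||% 0
  w <- options$weights %||% rep(1, nrow(network$reactions))
  if (!is.null(names(w))) w <- w[network$reactions$id]
  stopifnot(length(w) == nrow(network$reactions), all(w > 0))

  constraints <- as.data.frame(constraints)
  if (nrow(constraints) > 0L) {
    unknown <- setdiff(constraints$reaction_id, network$reactions$id)
    if (length(unknown) > 0L)
      stop("constraint references unknown reaction: ",
           paste(unknown, collapse = ", "))
    key <- unique(constraints[, intersect(c("day", "condition"), names(constraints)),
                              drop = FALSE])
    if (nrow(key) > 1L)
      stop("all constraints of one snapshot must share (day, condition)")
    if (!"tolerance" %in% names(constraints)) constraints$tolerance <- 0
    if (rel > 0)
      constraints$tolerance <- pmax(constraints$tolerance,
                                    rel * abs(constraints$value))
  }
  day <- if (nrow(constraints) > 0L && "day" %in% names(constraints))
    constraints$day[1L] else NA
  condition <- if (nrow(constraints) > 0L && "condition" %in% names(constraints))
    constraints$condition[1L] else NA

  rxn <- network$reactions
  n <- nrow(rxn)
  Sint <- s_internal(network)
  lb <- rxn$lb; ub <- rxn$ub
  Q <- diag(2 * w, n)

  # band constraints tighten the bounds; equality constraints become rows
  M <- matrix(0, 0L, n); b <- numeric(0L)
  eq_idx <- integer(0L)
  if (nrow(constraints) > 0L) {
    for (i in seq_len(nrow(constraints))) {
      j <- match(constraints$reaction_id[i], rxn$id)
      if (constraints$tolerance[i] > 0) {
        lb[j] <- max(lb[j], constraints$value[i] - constraints$tolerance[i])
        ub[j] <- min(ub[j], constraints$value[i] + constraints$tolerance[i])
      } else {
        row <- numeric(n); row[j] <- 1
        M <- rbind(M, row); b <- c(b, constraints$value[i])
        eq_idx <- c(eq_idx, i)
      }
    }
  }

  mk_solution <- function(v, status, diagnostic = NULL) {
    names(v) <- rxn$id
    resid <- numeric(nrow(constraints))
    if (nrow(constraints) > 0L) {
      dev <- abs(v[constraints$reaction_id] - constraints$value)
      resid <- pmax(0, dev - constraints$tolerance)
      names(resid) <- paste0(constraints$reaction_id, "=", constraints$value)
    }
    structure(list(fluxes = v, day = day, condition = condition,
                   objective_value = sum(v^2),
                   max_steady_state_residual =
                     if (nrow(Sint) > 0L) max(abs(Sint %*% v)) else 0,
                   constraint_residuals = resid,
                   status = status, diagnostic = diagnostic),
              class = "flux_solution")
  }

  Aeq <- rbind(Sint, M)
  beq <- c(numeric(nrow(Sint)), b)
  fit <- qp_active_set(Q, NULL, Aeq, beq, lb, ub, tol = tol)
  if (fit$status == "optimal") return(mk_solution(fit$x, "optimal"))

  # relaxation stage 1: minimise squared violation of measured equalities
  if (nrow(M) > 0L) {
    Q1 <- 2 * crossprod(M) + diag(1e-10, n)
    c1 <- as.numeric(-2 * crossprod(M, b))
    f1 <- qp_active_set(Q1, c1, Sint, numeric(nrow(Sint)), lb, ub, tol = tol)
    if (f1$status == "optimal") {
      r <- as.numeric(M %*% f1$x - b)
      f2 <- qp_active_set(Q, NULL, Aeq, c(numeric(nrow(Sint)), b + r),
                          lb, ub, tol = tol)
      if (f2$status == "optimal") return(mk_solution(f2$x, "relaxed"))
      return(mk_solution(f1$x, "relaxed"))
    }
  }

  # infeasible even after relaxation: diagnose the steady-state/bounds clash
  Qd <- 2 * crossprod(Sint) + diag(1e-10, n)
  fd <- qp_active_set(Qd, NULL, NULL, NULL, lb, ub, tol = tol)
  v <- fd$x
  imb <- if (nrow(Sint) > 0L) abs(as.numeric(Sint %*% v)) else numeric(0L)
  mets <- rownames(Sint)[order(imb, decreasing = TRUE)]
  at_lb <- rxn$id[abs(v - lb) <= 1e-6]
  at_ub <- rxn$id[abs(v - ub) <= 1e-6 & is.finite(ub)]
  diag_msg <- paste0(
    "no flux satisfies steady state within the bounds; ",
    "worst metabolite balance: ", paste(utils::head(mets, 3L), collapse = ", "),
    "; reactions at lower bound: ", paste(at_lb, collapse = ", "),
    "; at upper bound: ", paste(at_ub, collapse = ", "))
  sol <- mk_solution(rep(NA_real_, n), "infeasible", diag_msg)
  sol$objective_value <- NA_real_
  sol$max_steady_state_residual <- NA_real_
  sol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux snapshot [", x$status, "]",
      if (!is.na(x$day)) paste0(" day ", x$day),
      if (!is.na(x$condition)) paste0(" condition ", x$condition), "\n", sep = "")
  if (x$status != "infeasible") {
    cat("  sum of squared fluxes:", format(x$objective_value), "\n")
    cat("  max |S_int v|:", format(x$max_steady_state_residual), "\n")
    if (length(x$constraint_residuals) > 0L)
      cat("  max constraint violation:", format(max(x$constraint_residuals)), "\n")
  } else cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' Flux activity through an intermediate metabolite
#'
#' The flux activity of a metabolite is the sum of fluxes producing it
#' (equivalently, at steady state, consuming it): contributions are the
#' signed products `S[m, j] * v[j]`, positive ones summed into `producing`
#' and negative ones (negated) into `consuming`, so a reversible reaction
#' running backwards is counted on the correct side.
#'
#' @param solution a `flux_solution` with status other than "infeasible".
#' @param network the network the solution was computed on.
#' @param metabolite_id one or more metabolite ids.
#' @return data.frame with columns `metabolite_id`, `producing`,
#'   `consuming`, `day`, `condition` (units mmol/gDW/day).
#' @export
flux_activity <- function(solution, network, metabolite_id) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status == "infeasible")
    stop("cannot compute flux activity on an infeasible solution")
  unknown <- setdiff(metabolite_id, network$metabolites$id)
  if (length(unknown) > 0L)
    stop("unknown metabolite id: ", paste(unknown, collapse = ", "))
  v <- solution$fluxes[network$reactions$id]
  out <- lapply(metabolite_id, function(m) {
    contrib <- network$S[m, ] * v
    data.frame(metabolite_id = m,
               producing = sum(contrib[contrib > 0]),
               consuming = -sum(contrib[contrib < 0]),
               day = solution$day, condition = solution$condition,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the daily-snapshot flux time course
#'
#' Solves one QP snapshot per `(day, condition)` constraint set and
#' computes flux activities for a watchlist of intermediate metabolites
#' (for example the tetrahydrofolate and S-adenosyl-methionine cycle
#' intermediates).
#'
#' @param network a [reaction_network()].
#' @param constraints data.frame of measured constraints with `day` and
#'   `condition` columns; each `(day, condition)` group is solved
#'   independently.
#' @param watchlist character vector of metabolite ids (may be empty, in
#'   which case the activity table is empty but solutions are returned).
#' @param days optional vector of days expected per condition; `(day,
#'   condition)` pairs lacking constraints are skipped with a message.
#' @param options passed to [solve_snapshot_fluxes()].
#' @return list with `solutions` (list of `flux_solution`), `fluxes`
#'   (long data.frame: condition, day, reaction_id, flux) and `activity`
#'   (condition, day, metabolite_id, producing, consuming).
#' @export
run_flux_timecourse <- function(network, constraints, watchlist = character(0L),
                                days = NULL, options = list()) {
  constraints <- as.data.frame(constraints)
  stopifnot(nrow(constraints) > 0L,
            all(c("day", "condition") %in% names(constraints)))
  groups <- split(constraints,
                  list(constraints$condition, constraints$day), drop = TRUE)
  if (!is.null(days)) {
    have <- unique(constraints[, c("condition", "day")])
    for (cond in unique(have$condition)) {
      missing_days <- setdiff(days, have$day[have$condition == cond])
      if (length(missing_days) > 0L)
        message("skipping condition ", cond, ", day(s) ",
                paste(missing_days, collapse = ", "), ": no constraints")
    }
  }
  solutions <- list(); flux_rows <- list(); act_rows <- list()
  for (g in groups) {
    sol <- solve_snapshot_fluxes(network, g, options)
    key <- paste(sol$condition, sol$day, sep = ":")
    solutions[[key]] <- sol
    if (sol$status == "infeasible") {
      warning("snapshot ", key, " infeasible: ", sol$diagnostic)
      next
    }
    flux_rows[[key]] <- data.frame(condition = sol$condition, day = sol$day,
                                   reaction_id = names(sol$fluxes),
                                   flux = unname(sol$fluxes),
                                   stringsAsFactors = FALSE)
    if (length(watchlist) > 0L) {
      act <- flux_activity(sol, network, watchlist)
      act_rows[[key]] <- act[, c("condition", "day", "metabolite_id",
                                 "producing", "consuming")]
    }
  }
  empty_act <- data.frame(condition = character(0L), day = numeric(0L),
                          metabolite_id = character(0L),
                          producing = numeric(0L), consuming = numeric(0L))
  list(solutions = solutions,
       fluxes = if (length(flux_rows)) do.call(rbind, c(flux_rows, make.row.names = FALSE)) else NULL,
       activity = if (length(act_rows)) do.call(rbind, c(act_rows, make.row.names = FALSE)) else empty_act)
}
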