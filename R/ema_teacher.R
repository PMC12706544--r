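# Momentum (EMA) teacher: an exponentially smoothed copy of the student's
# parameters, updated as theta_teacher <- gamma * theta_teacher + (1 - gamma) *
# theta_student after every optimizer step, plus the epoch gate that decides
# when the distillation loss term becomes active.

#' Validate a parameter set
#'
#' A parameter set is an ordered named list of finite numeric arrays covering
#' every learnable entry of a model. Two sets are compatible when names, order
#' and shapes match exactly.
#'
#' @param params named list of numeric arrays.
#' @return the validated list, invisibly classed as `parameter_set`.
#' @export
as_parameter_set <- function(params) {
  stopifnot(is.list(params), length(params) > 0L)
  nm <- names(params)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("parameter set entries must have unique non-empty names")
  }
  for (k in nm) {
    if (!is.numeric(params[[k]])) stop(sprintf("entry '%s' is not numeric", k))
    if (any(!is.finite(params[[k]]))) stop(sprintf("entry '%s' has non-finite values", k))
  }
  class(params) <- c("parameter_set", "list")
  params
}

# returns NULL if compatible, else a message naming the first offending entry
params_incompatibility <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    na <- names(a); nb <- names(b)
    bad <- union(setdiff(na, nb), setdiff(nb, na))
    if (length(bad) == 0L) bad <- na[na != nb][1L]
    return(sprintf("parameter names/order differ (first offender: '%s')", bad[1L]))
  }
  for (k in names(a)) {
    da <- dim(a[[k]]) %||% length(a[[k]])
    db <- dim(b[[k]]) %||% length(b[[k]])
    if (!identical(as.integer(da), as.integer(db))) {
      return(sprintf("entry '%s' has shape %s vs %s", k,
                     paste(da, collapse = "x"), paste(db, collapse = "x")))
    }
  }
  NULL
}

#' Initialize the momentum teacher
#'
#' The teacher starts as an exact copy of the student. Every entry of the
#' parameter set — learnable weights and any running statistics — is covered
#' by the moving average, so the teacher is a fully functional inference model
#' at all times.
#'
#' @param student a [as_parameter_set()]-valid parameter set.
#' @param gamma momentum coefficient in `[0, 1]`; the default 0.90 is the
#'   momentum setting used for all experiments.
#' @param distill_start_epoch first (1-based) epoch in which the distillation
#'   loss is applied; the default 7 delays distillation until after the sixth
#'   training epoch.
#' @return a `teacher_state` list with fields `params`, `gamma`,
#'   `distill_start_epoch` and `updates_applied`.
#' @export
init_teacher <- function(student, gamma = 0.90, distill_start_epoch = 7L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("init_teacher: gamma must lie in [0, 1]")
  }
  if (!is.numeric(distill_start_epoch) || distill_start_epoch < 1) {
    stop("init_teacher: distill_start_epoch must be a positive integer")
  }
  student <- as_parameter_set(student)
  params <- lapply(student, function(a) a + 0) # force an independent copy
  class(params) <- class(student)
  structure(
    list(params = params, gamma = gamma,
         distill_start_epoch = as.integer(distill_start_epoch),
         updates_applied = 0L),
    class = "teacher_state"
  )
}

#' One momentum update of the teacher
#'
#' Applies `theta_teacher <- gamma * theta_teacher + (1 - gamma) *
#' theta_student` element-wise to every entry. `gamma = 1` is a fixed point
#' (teacher never moves); `gamma = 0` copies the student. The student is never
#' modified.
#'
#' @param state a `teacher_state` from [init_teacher()].
#' @param student the student's current parameter set, compatible with the
#'   teacher's.
#' @return the updated `teacher_state` with `updates_applied` incremented.
#' @export
ema_update <- function(state, student) {
  stopifnot(inherits(state, "teacher_state"))
  bad <- params_incompatibility(state$params, student)
  if (!is.null(bad)) stop("ema_update: incompatible parameter sets: ", bad)
  g <- state$gamma
  if (g == 0) {
    state$params[] <- lapply(student, function(a) a + 0)
  } else if (g != 1) {
    for (k in names(state$params)) {
      state$params[[k]] <- g * state$params[[k]] + (1 - g) * student[[k]]
    }
  }
  state$updates_applied <- state$updates_applied + 1L
  state
}

#' Closed form of repeated momentum updates under a constant student
#'
#' After `t` updates against a fixed student value `theta_s`, a teacher entry
#' initialized at `theta0` equals `gamma^t * theta0 + (1 - gamma^t) * theta_s`.
#' Used as an independent oracle for [ema_update()].
#'
#' @param theta0 initial teacher value.
#' @param theta_s constant student value.
#' @param gamma momentum coefficient in `[0, 1]`.
#' @param t non-negative integer number of updates.
#' @return the exact teacher value after `t` updates.
#' @export
ema_closed_form <- function(theta0, theta_s, gamma, t) {
  stopifnot(t >= 0)
  gt <- gamma^t
  gt * theta0 + (1 - gt) * theta_s
}

#' Is the distillation loss active in a given epoch?
#'
#' Epochs are 1-based. With the default schedule (`distill_start_epoch = 7`)
#' the distillation term is inactive for epochs 1-6 and active from epoch 7
#' onward, i.e. only after the sixth training epoch has completed.
#'
#' @param epoch 1-based epoch index.
#' @param state a `teacher_state`, or a plain positive integer taken as
#'   `distill_start_epoch`.
#' @return logical flag.
#' @export
distill_active <- function(epoch, state) {
  if (!is.numeric(epoch) || length(epoch) != 1L || epoch < 1) {
    stop("distill_active: epoch must be a positive (1-based) integer")
  }
  start <- if (inherits(state, "teacher_state")) state$distill_start_epoch else state
  epoch >= start
}
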