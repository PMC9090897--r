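# Declarative mapping from design factors (and trial number) to free
# diffusion parameters.  A model spec records, for each of a, v, z, t0,
# whether the parameter is fixed or free and which design factors split it
# into condition cells; dynamic models add an identity-link trial-number
# regression (one slope per cell of the regressed parameter), with resolved
# values clipped back to the valid domain.

FACTOR_ORDER <- c("stimulus_frequency", "matching_condition",
                  "shape_association")

# clipping domains applied after trial-number regression
CLIP <- list(a = c(0.05, 10), v = c(-25, 25), z = c(0.01, 0.99),
             t0 = c(0, Inf))

factor_levels <- function(experiment) {
  freq <- if (experiment == 1) "equal" else
    c("self_frequent", "friend_frequent")
  list(stimulus_frequency = freq,
       matching_condition = c("matching", "nonmatching"),
       shape_association = c("self", "friend"))
}

# cell labels for a parameter split by `by` (canonical factor order);
# character(0) factors -> single unlabelled cell ""
param_cells <- function(by, levels) {
  by <- FACTOR_ORDER[FACTOR_ORDER %in% by]
  if (length(by) == 0L) return("")
  g <- expand.grid(rev(lapply(by, function(f) levels[[f]])),
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(by)), drop = FALSE]
  names(g) <- by
  apply(g, 1L, paste, collapse = ".")
}

#' Construct a diffusion-model specification
#'
#' Defines which diffusion parameters are free, which design factors they
#' vary over, and which parameters receive an identity-link trial-number
#' regression. The inter-trial variabilities `sv`, `st`, `sz` are always
#' global free scalars; responses are always response coded (upper
#' boundary = matching response).
#'
#' @param label model label, e.g. `"m1"`.
#' @param experiment experiment id (1, 2 or 3); determines the available
#'   stimulus-frequency levels.
#' @param v_by factors the drift rate varies over.
#' @param z either `"free"` or a fixed numeric value (e.g. `0.5` for no
#'   bias).
#' @param z_by factors the starting point varies over (only if free).
#' @param a_by factors the boundary separation varies over.
#' @param regress character subset of `c("a", "v", "z")`: parameters whose
#'   cells receive a trial-number slope.
#' @return An object of class `ddm_model_spec`.
#' @export
model_spec <- function(label, experiment, v_by = "matching_condition",
                       z = "free", z_by = character(), a_by = character(),
                       regress = character()) {
  stopifnot(experiment %in% 1:3)
  lv <- factor_levels(experiment)
  ok_f <- names(lv)
  if (!all(v_by %in% ok_f) || !all(z_by %in% ok_f) || !all(a_by %in% ok_f))
    stop("unknown design factor", call. = FALSE)
  if (!all(regress %in% c("a", "v", "z")))
    stop("regress must be a subset of c('a','v','z')", call. = FALSE)
  z_fixed <- NULL
  if (is.numeric(z)) {
    z_fixed <- z
    if (length(z_by)) stop("a fixed z cannot vary over factors", call. = FALSE)
    if ("z" %in% regress)
      stop("a fixed z cannot carry a trial-number slope", call. = FALSE)
  } else if (!identical(z, "free")) {
    stop("z must be 'free' or a fixed numeric value", call. = FALSE)
  }
  par <- list(
    a = list(fixed = NULL, by = a_by, cells = param_cells(a_by, lv),
             slope = "a" %in% regress),
    v = list(fixed = NULL, by = v_by, cells = param_cells(v_by, lv),
             slope = "v" %in% regress),
    z = list(fixed = z_fixed, by = z_by, cells = param_cells(z_by, lv),
             slope = "z" %in% regress),
    t0 = list(fixed = NULL, by = character(), cells = "", slope = FALSE)
  )
  structure(list(label = label, experiment = experiment, par = par,
                 response_coded = TRUE),
            class = "ddm_model_spec")
}

#' The model ladders of the three experiments
#'
#' Returns the ordered comparison ladder fitted in each experiment.
#' Experiment 1 (equivalent context): four models crossing a
#' matching-condition vs shape-by-matching drift split with a fixed
#' (`z = 0.5`) vs free starting point. Experiment 2 (confirmatory
#' context): the default model (drift split by frequency, shape and
#' matching; free starting point), then starting point split by stimulus
#' frequency, then boundary separation split by stimulus frequency.
#' Experiment 3 (dis-confirmatory context): the experiment-2 ladder with
#' trial-number regression terms on `z`, `v` and `a`.
#'
#' @param experiment 1, 2 or 3.
#' @return Named list of [model_spec()] objects (`"m1"`, `"m2"`, ...).
#' @export
build_model_ladder <- function(experiment) {
  if (!experiment %in% 1:3) stop("unknown experiment id", call. = FALSE)
  if (experiment == 1) {
    specs <- list(
      model_spec("m1", 1, v_by = "matching_condition", z = 0.5),
      model_spec("m2", 1, v_by = "matching_condition", z = "free"),
      model_spec("m3", 1, v_by = c("shape_association", "matching_condition"),
                 z = 0.5),
      model_spec("m4", 1, v_by = c("shape_association", "matching_condition"),
                 z = "free"))
  } else {
    reg <- if (experiment == 3) c("z", "v", "a") else character()
    v_all <- c("stimulus_frequency", "shape_association", "matching_condition")
    specs <- list(
      model_spec("m1", experiment, v_by = v_all, z = "free", regress = reg),
      model_spec("m2", experiment, v_by = v_all, z = "free",
                 z_by = "stimulus_frequency", regress = reg),
      model_spec("m3", experiment, v_by = v_all, z = "free",
                 a_by = "stimulus_frequency", regress = reg))
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "label"))
}

# ---- parameter labelling --------------------------------------------------

param_label <- function(p, cell) if (cell == "") p else paste0(p, "(", cell, ")")
slope_label <- function(p, cell) paste0("slope_", param_label(p, cell))

#' Group-level parameter labels of a model spec
#'
#' @param spec a [model_spec()].
#' @param include_variabilities include `sv`, `st`, `sz`.
#' @return Character vector of labels (means, then slopes, then
#'   variabilities).
#' @export
spec_labels <- function(spec, include_variabilities = TRUE) {
  out <- character()
  for (p in c("a", "v", "z", "t0")) {
    pp <- spec$par[[p]]
    if (!is.null(pp$fixed)) next
    out <- c(out, vapply(pp$cells, function(cl) param_label(p, cl), ""))
  }
  for (p in c("a", "v", "z")) {
    pp <- spec$par[[p]]
    if (pp$slope)
      out <- c(out, vapply(pp$cells, function(cl) slope_label(p, cl), ""))
  }
  if (include_variabilities) out <- c(out, "sv", "st", "sz")
  unname(out)
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat("Model", x$label, "(experiment", x$experiment, ", response coded)\n")
  for (p in c("a", "v", "z", "t0")) {
    pp <- x$par[[p]]
    if (!is.null(pp$fixed)) {
      cat("  ", p, ": fixed at ", pp$fixed, "\n", sep = "")
    } else {
      by <- if (length(pp$by)) paste(pp$by, collapse = " x ") else "global"
      cat("  ", p, ": free, ", by,
          if (pp$slope) " + trial-number slope" else "", "\n", sep = "")
    }
  }
  cat("   sv, st, sz: global free scalars\n")
  invisible(x)
}

# integer cell index of each trial for parameter p
cell_index <- function(spec, p, trials) {
  pp <- spec$par[[p]]
  if (length(pp$by) == 0L) return(rep(1L, nrow(trials)))
  by <- FACTOR_ORDER[FACTOR_ORDER %in% pp$by]
  key <- do.call(paste, c(lapply(by, function(f) as.character(trials[[f]])),
                          sep = "."))
  idx <- match(key, pp$cells)
  if (anyNA(idx))
    stop("trials contain design cells not covered by the model spec",
         call. = FALSE)
  idx
}

# Resolve per-trial parameter vectors from a named draw of group-level
# values.  `draw` must contain every free mean (and slope / variability)
# label of the spec.  Regression: value = base + slope * trial_number,
# identity link, then clipped to the parameter domain.
resolve_params <- function(spec, draw, trials) {
  need <- spec_labels(spec)
  miss <- setdiff(need, names(draw))
  if (length(miss))
    stop("draw is missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(trials)
  out <- list()
  for (p in c("a", "v", "z", "t0")) {
    pp <- spec$par[[p]]
    if (!is.null(pp$fixed)) {
      val <- rep(pp$fixed, n)
    } else {
      idx <- cell_index(spec, p, trials)
      base <- unname(draw[vapply(pp$cells, function(cl) param_label(p, cl), "")])
      val <- base[idx]
      if (isTRUE(pp$slope)) {
        sl <- unname(draw[vapply(pp$cells, function(cl) slope_label(p, cl), "")])
        val <- val + sl[idx] * trials$trial_number
      }
      val <- pmin(pmax(val, CLIP[[p]][1]), CLIP[[p]][2])
    }
    out[[p]] <- val
  }
  out$sv <- unname(draw["sv"]); out$st <- unname(draw["st"])
  out$sz <- unname(draw["sz"])
  out
}

#' Resolve the diffusion parameters of a single trial
#'
#' Applies a model specification to one trial: selects the condition cell
#' of every factor-split parameter, adds `slope * trial_number` for
#' regressed parameters, clips to the valid domain (`z` to
#' `[0.01, 0.99]`, `a` to `[0.05, 10]`, `t0` to be non-negative) and
#' returns a [ddm_params()] object.
#'
#' @param spec a [model_spec()].
#' @param draw named numeric vector with one value per label in
#'   [spec_labels()].
#' @param trial a one-row trial data frame.
#' @return A [ddm_params()] object.
#' @export
params_for_trial <- function(spec, draw, trial) {
  r <- resolve_params(spec, draw, trial)
  ddm_params(a = r$a[1], v = r$v[1], z = r$z[1], t0 = r$t0[1],
             sv = r$sv, st = r$st, sz = r$sz)
}

#' Serialise / parse a model specification
#'
#' `format_model_spec()` renders a spec as a small key/value text block;
#' `parse_model_spec()` inverts it. Round-tripping is the identity.
#'
#' @param spec a [model_spec()].
#' @return A character scalar (`format_model_spec`) or a
#'   [model_spec()] (`parse_model_spec`).
#' @export
format_model_spec <- function(spec) {
  z <- spec$par$z
  zs <- if (!is.null(z$fixed)) format(z$fixed) else "free"
  reg <- c("a", "v", "z")[vapply(c("a", "v", "z"),
                                 function(p) isTRUE(spec$par[[p]]$slope),
                                 NA)]
  paste0("label: ", spec$label, "\n",
         "experiment: ", spec$experiment, "\n",
         "v_by: ", paste(spec$par$v$by, collapse = ","), "\n",
         "z: ", zs, "\n",
         "z_by: ", paste(spec$par$z$by, collapse = ","), "\n",
         "a_by: ", paste(spec$par$a$by, collapse = ","), "\n",
         "regress: ", paste(reg, collapse = ","), "\n")
}

#' @rdname format_model_spec
#' @param text output of `format_model_spec()`.
#' @export
parse_model_spec <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""),
                          vapply(kv, `[[`, "", 1))
  split1 <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]] else character()
  zv <- vals[["z"]]
  z <- if (identical(zv, "free")) "free" else as.numeric(zv)
  model_spec(label = vals[["label"]],
             experiment = as.integer(vals[["experiment"]]),
             v_by = split1(vals[["v_by"]]), z = z,
             z_by = split1(vals[["z_by"]]), a_by = split1(vals[["a_by"]]),
             regress = split1(vals[["regress"]]))
}
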