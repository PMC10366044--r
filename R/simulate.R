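#' Default simulation configuration
#'
#' All parameters of the three-stage adhesion experiment, in a nested list
#' that can also be read from a YAML file ([read_config()]). Densities are in
#' molecules/µm², lengths in µm, times in s, energies in J/mol.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    r0 = 10, n_nodes = 200L, N_receptors = 24000,
    model = "base",                 # "base" or "split"
    immobile_frac = 0.23,           # split model only
    chemistry = list(dG0 = -32949.0, T = 310.15, cLmax = 16000,
                     cLav = 90, ell_chem = 0.2, D_R = 0.198),
    stages = list(t_attach = 300, t_transloc = 600, t_end = 7200,
                  dt_stage = c(0.5, 0.1, 0.05), substeps = 100L),
    contact = list(a_attach = 3.35, a_final = 19.8),
    t_stop = NULL,                  # optional early stop [s]
    output_every = 10,              # totals/fields cadence [s]
    store_fields = TRUE,
    mass = "lumped",
    output_dir = NULL,              # if set, totals CSV flushed there
    seed = NULL                     # reserved; the simulation is deterministic
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it (recursively) into
#' [default_config()], so partial files are fine.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), user)
  if (!is.null(cfg$stages$dt_stage)) cfg$stages$dt_stage <- as.numeric(cfg$stages$dt_stage)
  cfg
}

#' Run the three-stage adhesion simulation
#'
#' Executes the staggered loop: at every mechanical step the prescribed
#' kinematics (volume-conserving spherical-cap family driven by the
#' piecewise-linear contact-radius schedule) is updated first, then the
#' chemo-transport problem is advanced over the step with `substeps`
#' sub-increments. The coupling is strictly one-way (kinematics to
#' chemistry). During the diffusion stage the shape is frozen, so steps are
#' batched between output times.
#'
#' @param config Configuration list (see [default_config()]); entries given
#'   in `...` override it.
#' @param ... Named overrides merged into `config`.
#' @return Object of class `"vegfr2_trajectory"`: list with `times`, a
#'   `totals` data frame (one row per output time, see [integrate_totals()]),
#'   `fields` (list of field states, if stored), `frames` (data frame of
#'   shape descriptors t, a, h, R_s, area, lambda_a), `mesh`, `params`,
#'   `plan`, `config`, `model`.
#' @export
run_simulation <- function(config = default_config(), ...) {
  dots <- list(...)
  if (length(dots)) config <- modifyList(config, dots)
  mesh <- build_meridian_mesh(config$r0, config$n_nodes)
  p <- do.call(chemistry_params, config$chemistry)
  st <- config$stages
  plan <- stage_plan(st$t_attach, st$t_transloc, st$t_end,
                     st$dt_stage, st$substeps)
  ops <- assemble_operators(mesh, p$D_R, mass = config$mass)
  V0 <- 4 / 3 * pi * config$r0^3
  a_of_t <- function(t) contact_radius_schedule(t, plan,
                                                config$contact$a_attach,
                                                config$contact$a_final)
  frame_at <- function(t) map_reference_to_current(mesh, cap_shape(a_of_t(t), V0), t)

  model <- match.arg(config$model, c("base", "split"))
  state <- if (model == "base") {
    init_state_base(mesh, N_total = config$N_receptors)
  } else {
    init_state_split(mesh, N_total = config$N_receptors,
                     immobile_frac = config$immobile_frac)
  }
  stepper <- if (model == "base") step_base else step_split

  t_stop <- if (is.null(config$t_stop)) plan$t_end else config$t_stop
  out_dt <- config$output_every

  frames_meta <- list()
  totals <- list()
  fields <- list()
  record <- function(state, frame) {
    i <- length(totals) + 1L
    totals[[i]] <<- integrate_totals(state, mesh, frame)
    cap <- cap_shape(frame$a, V0)
    frames_meta[[i]] <<- data.frame(t = state$t, a = frame$a, h = cap$h,
                                    R_s = cap$R_s, area = frame$area,
                                    lambda_a = frame$lambda_a[1])
    if (isTRUE(config$store_fields)) fields[[i]] <<- state
  }

  frame <- frame_at(0)
  record(state, frame)
  next_out <- out_dt

  flush_partial <- function() {
    if (!is.null(config$output_dir) && length(totals)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      tr <- list(totals = do.call(rbind, totals))
      class(tr) <- "vegfr2_trajectory"
      write_totals_csv(tr, file.path(config$output_dir, "totals.csv"))
    }
  }
  on.exit(flush_partial())

  stage_bounds <- c(0, plan$t_attach, plan$t_transloc, plan$t_end)
  for (s in 1:3) {
    t0 <- stage_bounds[s]; t1 <- min(stage_bounds[s + 1], t_stop)
    if (t0 >= t_stop) break
    dt <- plan$dt_stage[s]
    if (s < 3) {
      nstep <- ceiling((t1 - t0 - 1e-9) / dt)
      for (k in seq_len(nstep)) {
        t_next <- min(t0 + k * dt, t1)
        frame_next <- frame_at(t_next)
        state <- stepper(state, frame, frame_next, t_next - state$t, ops, p,
                         plan$substeps)
        frame <- frame_next
        if (state$t >= next_out - 1e-9 || abs(state$t - t1) < 1e-9) {
          record(state, frame)
          if (state$t >= next_out - 1e-9) next_out <- next_out + out_dt
        }
      }
    } else {
      # diffusion stage: shape frozen, batch sub-steps between output times
      sub_dt <- dt / plan$substeps
      while (state$t < t1 - 1e-9) {
        t_next <- min(max(next_out, state$t + out_dt), t1)
        nsub <- max(1L, as.integer(round((t_next - state$t) / sub_dt)))
        state <- stepper(state, frame, frame, t_next - state$t, ops, p, nsub)
        record(state, frame)
        next_out <- next_out + out_dt
      }
    }
    if (state$t >= t_stop - 1e-9) break
  }
  on.exit()
  traj <- structure(
    list(times = vapply(totals, function(x) x$t, numeric(1)),
         totals = do.call(rbind, totals),
         fields = if (isTRUE(config$store_fields)) fields else NULL,
         frames = do.call(rbind, frames_meta),
         mesh = mesh, params = p, plan = plan, config = config,
         model = model),
    class = "vegfr2_trajectory")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_totals_csv(traj, file.path(config$output_dir, "totals.csv"))
  }
  traj
}

#' @export
print.vegfr2_trajectory <- function(x, ...) {
  n <- nrow(x$totals)
  cat("VEGFR2 relocation trajectory (", x$model, " model): ",
      n, " output times over [0, ", max(x$times), "] s\n", sep = "")
  last <- x$totals[n, ]
  cat(sprintf("  final: N_C = %.1f, N_R_free = %.1f (total %.1f)\n",
              last$N_C, last$N_R_free, last$N_C + last$N_R_free))
  invisible(x)
}
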