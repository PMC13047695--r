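# Composite runbooks: the standard restrained-production protocol
# (minimize -> positionally restrained equilibration -> ramped restrained
# production) and the monomer detachment assay.

#' Restrained production protocol
#'
#' Stages: steepest-descent minimization; a short equilibration with
#' positional restraints on all beads; production with the CS (and
#' optionally NOE) restraints ramped in. Emits a per-frame report with
#' restraint energies and the scaled CS RMSD.
#'
#' @param config list with fields:
#'   \describe{
#'     \item{structure}{starting \code{cg_structure} (required)}
#'     \item{model}{\code{shift_model} (required with \code{shift_table})}
#'     \item{shift_table}{experimental secondary \code{shift_table}}
#'     \item{restraints}{optional \code{cg_restraints} (NOE)}
#'     \item{k_cs, ramp_rate}{CS restraint plateau and per-step ramp
#'       (defaults 25, 0.001)}
#'     \item{equil_steps, production_steps}{stage lengths (defaults 500,
#'       5000)}
#'     \item{posres_k}{equilibration positional-restraint constant
#'       (default 1000)}
#'     \item{report_every, temperature, seed, dt, gamma}{run controls}
#'     \item{ff_params}{toy force-field overrides}
#'     \item{time_averaged_noe}{logical (default FALSE)}
#'   }
#' @return list: \code{trajectory}, \code{report} (data.frame with columns
#'   step, time_ps, energies, k_cs, cs_rmsd), \code{final_state}.
#' @export
restrained_production <- function(config) {
  cfg <- utils::modifyList(list(
    k_cs = 25, ramp_rate = 0.001, equil_steps = 500, production_steps = 5000,
    posres_k = 1000, report_every = 100, temperature = 300, seed = 1,
    dt = 0.01, gamma = 0.01, ff_params = list(), time_averaged_noe = FALSE,
    per_atom_sd = NULL), config)
  stopif(is.null(cfg$structure), "config needs a structure")
  emb <- blosum_embedding()
  ff <- toy_forcefield(cfg$structure, cfg$ff_params)

  st <- sim_state(cfg$structure, temperature = cfg$temperature, seed = cfg$seed)
  st <- minimize(st, list(ff))

  if (cfg$equil_steps > 0) {
    eq <- run_dynamics(st, list(ff, position_restraint(st$coords, cfg$posres_k)),
                       n_steps = cfg$equil_steps,
                       report_every = max(cfg$equil_steps, 1),
                       dt = cfg$dt, gamma = cfg$gamma)
    st <- attr(eq, "final_state")
  }

  providers <- list(ff)
  have_cs <- !is.null(cfg$model) && !is.null(cfg$shift_table)
  if (have_cs) {
    cs_cfg <- cs_restraint_config(k_cs = cfg$k_cs, ramp_rate = cfg$ramp_rate,
                                  k_max = cfg$k_cs, epsilon = cfg$model$epsilon)
    providers <- c(providers,
                   list(cs_restraint_provider(cfg$model, cfg$shift_table,
                                              cs_cfg, embedding = emb)))
  }
  if (!is.null(cfg$restraints)) {
    providers <- c(providers,
                   list(noe_restraint_provider(cfg$restraints,
                                               time_averaged = cfg$time_averaged_noe,
                                               dt = cfg$dt)))
  }
  st$step <- 0L
  tr <- run_dynamics(st, providers, n_steps = cfg$production_steps,
                     report_every = cfg$report_every,
                     dt = cfg$dt, gamma = cfg$gamma)
  report <- attr(tr, "report")
  if (have_cs) {
    sds <- cfg$per_atom_sd %||% stats::setNames(rep(1, 6), ATOM_TYPES)
    report$cs_rmsd <- vapply(tr$frames, function(fr) {
      cs_rmsd_scaled(predict_shifts(cfg$model, set_coords(cfg$structure, fr),
                                    embedding = emb),
                     cfg$shift_table, sds)
    }, numeric(1))
  }
  list(trajectory = tr, report = report, final_state = attr(tr, "final_state"))
}

# bead-contact count between two index sets (strict cutoff)
count_contacts <- function(coords, sel_a, sel_b, cutoff) {
  da <- coords[sel_a, , drop = FALSE]
  db <- coords[sel_b, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(da))) {
    d2 <- rowSums(sweep(db, 2, da[i, ])^2)
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

#' Monomer detachment assay
#'
#' Runs \code{n_replicas} simulations in which the NOE restraints crossing
#' the monomer selection are removed, counts monomer-to-remainder bead
#' contacts (strict distance < cutoff) per frame, and flags a replica as
#' detached if any frame has zero contacts.
#'
#' @param config as for \code{\link{restrained_production}}, plus
#'   \code{monomer}: integer vector of bead indices forming the monomer.
#' @param n_replicas number of replicas (seeds are base seed + replica
#'   index).
#' @param contact_cutoff nm (default 0.8).
#' @return list: \code{detached} logical per replica, \code{contacts} list
#'   of per-frame contact counts, \code{histograms} list of contact-count
#'   tables.
#' @export
detachment_assay <- function(config, n_replicas = 3, contact_cutoff = 0.8) {
  sel <- config$monomer
  stopif(is.null(sel) || length(sel) == 0, "empty monomer selection")
  all_beads <- seq_len(nrow(config$structure$coords))
  rest <- setdiff(all_beads, sel)
  stopif(length(rest) == 0, "monomer selection covers the whole system")
  if (!is.null(config$restraints)) {
    r <- config$restraints
    crossing <- (r$bead_i %in% sel) != (r$bead_j %in% sel)
    config$restraints <- if (all(crossing)) NULL else cg_restraints(r[!crossing, ])
  }
  base_seed <- config$seed %||% 1
  detached <- logical(n_replicas)
  contacts <- vector("list", n_replicas)
  for (rep_i in seq_len(n_replicas)) {
    config$seed <- base_seed + rep_i
    out <- restrained_production(config)
    cc <- vapply(out$trajectory$frames, count_contacts, integer(1),
                 sel_a = sel, sel_b = rest, cutoff = contact_cutoff)
    contacts[[rep_i]] <- cc
    detached[rep_i] <- any(cc == 0)
  }
  list(detached = detached, contacts = contacts,
       histograms = lapply(contacts, table))
}
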