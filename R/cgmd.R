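# R-side surface of the coarse-grained simulator: parameter and geometry
# constructors, bead mapping, single calls into the compiled Langevin
# engine, and simulated force-profile (CGMD-FP) generation.

KCAL_PER_EV <- 23.0605
PN_PER_KCAL_MOL_NM <- 6.9477 # 1 kcal/mol/nm in pN
BOLTZMANN_KCAL <- 0.0019872041 # kcal/mol/K

#' Simulation parameters for the coarse-grained integrator
#'
#' Defaults are desk scale: 10 replicates, 0.6 s of force sampling per
#' replicate, an accelerated growth (translation) rate, and 8-residue
#' length increments. `scale = "full"` switches to the full protocol (100
#' replicates, 6 s sampling at 3 ms intervals, 5 aa/s translation,
#' 4-residue increments); both run the same engine.
#'
#' @param dt Timestep (s); default 300 ns.
#' @param D Bead diffusion coefficient (nm^2/s); default 253.
#' @param temperature Kelvin; default 310 (kBT ~ 0.616 kcal/mol).
#' @param membrane_potential Volts, cytoplasm minus periplasm; default
#'   -0.1 V (cytoplasm negative). Set 0 to disable.
#' @param translation_rate Growth rate during the translation phase (aa/s).
#' @param force_sample_interval Seconds between force samples; default 3 ms.
#' @param force_sample_duration Seconds of sampling per replicate.
#' @param replicates Independent replicates per length.
#' @param initial_translated Residues present at the start of growth.
#' @param first_measured_length First sampled nascent-chain length (aa).
#' @param length_increment Spacing of sampled lengths (aa).
#' @param equilibration Seconds of equilibration between the end of growth
#'   and the first force sample.
#' @param k_bond Bond stiffness (kcal/mol/nm^2); default gives ~10%
#'   bond-length fluctuation.
#' @param r_bond Bead-bead bond length (nm).
#' @param k_anchor C-terminal anchor stiffness (kcal/mol/nm^2).
#' @param k_wall Wall repulsion stiffness (kcal/mol/nm^2).
#' @param k_head Headgroup-crossing barrier (kcal/mol) paid by any bead
#'   crossing a membrane face outside the aqueous pore; makes the lipid
#'   interior reachable through the lateral gate (from inside the channel)
#'   rather than from the membrane surfaces.
#' @param k_excl,d_excl Short-range bead-bead repulsion (stiffness,
#'   kcal/mol/nm^2, and contact distance, nm) applied only inside the
#'   confined channel region below the tunnel exit, where the nascent
#'   chain is single-file and beads cannot pass one another; set
#'   `k_excl = 0` to disable.
#' @param transfer_scale Well-depth multiplier applied to bead transfer
#'   free energies inside the engine (dimensionless; default 2). The
#'   pairwise interaction strengths of this class of model are calibration
#'   choices; the default is set so that a 21-residue poly-Leu-like helix
#'   robustly partitions into the bilayer.
#' @param gate_dG0 Lateral-gate free energy, open minus closed, with an
#'   empty gate (kcal/mol; positive favours closed).
#' @param gate_coupling Coupling of gate opening to the summed
#'   hydrophobicity of beads in the gate region (dimensionless).
#' @param gate_interval_steps Steps between gate flip attempts.
#' @param seed Master seed; replicate streams are derived from it.
#' @param scale `"desk"` (default) or `"full"` (the full measurement protocol).
#' @return A `cg_params` list.
#' @export
cg_params <- function(dt = 300e-9, D = 253, temperature = 310,
                      membrane_potential = -0.1,
                      translation_rate = NULL,
                      force_sample_interval = 3e-3,
                      force_sample_duration = NULL,
                      replicates = NULL,
                      initial_translated = 12L,
                      first_measured_length = 18L,
                      length_increment = NULL,
                      equilibration = 0.03,
                      k_bond = NULL, r_bond = 0.8,
                      k_anchor = 50, k_wall = 100,
                      k_head = 4, k_excl = 100, d_excl = 0.6,
                      transfer_scale = 2,
                      gate_dG0 = 2, gate_coupling = 1,
                      gate_interval_steps = 100L,
                      seed = 1L,
                      scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (is.null(translation_rate)) {
    translation_rate <- if (scale == "full") 5 else 500
  }
  if (is.null(force_sample_duration)) {
    force_sample_duration <- if (scale == "full") 6 else 0.6
  }
  if (is.null(replicates)) replicates <- if (scale == "full") 100L else 10L
  if (is.null(length_increment)) {
    length_increment <- if (scale == "full") 4L else 8L
  }
  kBT <- BOLTZMANN_KCAL * temperature
  if (is.null(k_bond)) k_bond <- kBT / (0.1 * r_bond)^2
  stopifnot(
    dt > 0, D > 0, temperature > 0, translation_rate > 0,
    force_sample_interval > dt, force_sample_duration >= 2 * force_sample_interval,
    replicates >= 1, initial_translated >= 3, length_increment >= 1
  )
  structure(
    list(
      dt = dt, D = D, temperature = temperature, kBT = kBT,
      membrane_potential = membrane_potential,
      translation_rate = translation_rate,
      force_sample_interval = force_sample_interval,
      force_sample_duration = force_sample_duration,
      replicates = as.integer(replicates),
      initial_translated = as.integer(initial_translated),
      first_measured_length = as.integer(first_measured_length),
      length_increment = as.integer(length_increment),
      equilibration = equilibration,
      k_bond = k_bond, r_bond = r_bond, k_anchor = k_anchor, k_wall = k_wall,
      k_head = k_head, k_excl = k_excl, d_excl = d_excl,
      transfer_scale = transfer_scale,
      gate_dG0 = gate_dG0, gate_coupling = gate_coupling,
      gate_interval_steps = as.integer(gate_interval_steps),
      seed = as.integer(seed), scale = scale
    ),
    class = "cg_params"
  )
}

#' Idealized ribosome / translocon / membrane geometry
#'
#' The membrane is a slab centered on z = 0; the translocon is an aqueous
#' pore through it on the z axis with a lateral-gate sector opening toward
#' +x; the (truncated) ribosome exit tunnel is a cylinder above the
#' membrane, with the peptidyl-transferase-center anchor at its top and a
#' gap between tunnel exit and membrane surface through which the chain can
#' escape into the cytoplasm. All structures are static except the gate
#' state. This is a parameterized idealization, not cryo-EM coordinates.
#'
#' @param slab_thickness Membrane thickness (nm).
#' @param r_pore Translocon pore radius (nm).
#' @param r_tunnel Exit-tunnel radius (nm).
#' @param tunnel_length Exit-tunnel length (nm); truncated relative to the
#'   real ~8-9 nm PTC-to-exit span, which is what makes a reporting shift
#'   necessary (see [estimate_tunnel_shift()]).
#' @param gap Distance between tunnel exit and membrane surface (nm).
#' @param taper_w z-width of the smooth lipid interface (nm).
#' @param r_switch_w Radial width of the pore-to-lipid transition (nm).
#' @param r_free Radius beyond which the bilayer is reachable regardless of
#'   the gate (fully integrated helices; nm).
#' @param sector_halfwidth_deg Lateral-gate sector half-width (degrees).
#' @param r_gate_region Radial extent of the region whose hydrophobic beads
#'   bias the gate open (nm).
#' @return A `cg_geometry` list, including the derived z coordinates.
#' @export
cg_geometry <- function(slab_thickness = 3.0, r_pore = 0.5, r_tunnel = 0.6,
                        tunnel_length = 2.0, gap = 0.8, taper_w = 0.3,
                        r_switch_w = 0.2, r_free = 2.0,
                        sector_halfwidth_deg = 60, r_gate_region = 0.9) {
  stopifnot(
    slab_thickness > 0, r_pore > 0, r_tunnel > 0, tunnel_length > 0,
    gap >= 0, r_free > r_pore
  )
  z_mem_top <- slab_thickness / 2
  structure(
    list(
      slab_thickness = slab_thickness, r_pore = r_pore, r_tunnel = r_tunnel,
      tunnel_length = tunnel_length, gap = gap, taper_w = taper_w,
      r_switch_w = r_switch_w, r_free = r_free,
      sector_halfwidth_deg = sector_halfwidth_deg,
      sector_halfwidth_rad = sector_halfwidth_deg * pi / 180,
      r_gate_region = r_gate_region,
      z_mem_top = z_mem_top, z_mem_bot = -z_mem_top,
      z_tun_bot = z_mem_top + gap,
      z_tun_top = z_mem_top + gap + tunnel_length
    ),
    class = "cg_geometry"
  )
}

#' Reporting shift implied by the truncated exit tunnel
#'
#' Simulated lengths are reported as `reported_N = length_aa + shift`,
#' compensating for the residues "missing" from the model's truncated exit
#' tunnel. The default shift is the difference between the number of
#' nascent-chain residues separating the PTC from the membrane in the real
#' system (~40-50 by real-time FRET and model-helix arrest-peptide
#' experiments; default 40) and the residues the model geometry itself
#' holds between anchor and membrane surface at the bead contour length
#' (0.8 nm per 3 residues). [align_profiles()] offers the alternative,
#' data-driven estimate against an experimental profile.
#'
#' @param geometry A [cg_geometry()].
#' @param ptc_to_membrane_residues Residues between the PTC and the
#'   membrane integration point in the real ribosome-translocon system;
#'   default 40.
#' @return Integer shift (residues).
#' @export
estimate_tunnel_shift <- function(geometry, ptc_to_membrane_residues = 40) {
  nm_per_residue <- 0.8 / 3 # bead contour length
  # span from the anchor (PTC) to the lateral gate at the slab center,
  # where integration begins
  model_span_res <- geometry$z_tun_top / nm_per_residue
  as.integer(round(ptc_to_membrane_residues - model_span_res))
}

#' Map an amino-acid sequence onto coarse-grained beads
#'
#' Three consecutive residues per bead, N-terminal residue first; a final
#' partial bead averages its one or two residues. Bead hydrophobicity is
#' the mean per-residue transfer free energy times 3 (kcal/mol; negative
#' favours the bilayer on the default biological scale); bead charge is the
#' summed formal charge (+1 K/R, -1 D/E).
#'
#' @param seq Amino-acid sequence.
#' @param scale_name Hydrophobicity scale; default `"biological"`.
#' @return A tibble: `bead`, `first_res`, `last_res`, `n_res`,
#'   `hydrophobicity`, `charge`.
#' @export
#' @examples
#' map_to_beads("KRDLLLNNN")
map_to_beads <- function(seq, scale_name = "biological") {
  scale <- get_scale(scale_name)
  ch <- aa_chars(seq)
  L <- length(ch)
  n_beads <- ceiling(L / 3)
  purrr::map(seq_len(n_beads), function(b) {
    first <- 3L * (b - 1L) + 1L
    last <- min(3L * b, L)
    res <- ch[first:last]
    tibble(
      bead = b, first_res = first, last_res = last, n_res = length(res),
      hydrophobicity = mean(scale[res]) * 3,
      charge = sum(AA_CHARGE[res])
    )
  }) %>% dplyr::bind_rows()
}

# Internal: geometry/params lists in the form the C++ engine expects.
cpp_geom <- function(geometry) {
  out <- geometry[c(
    "z_mem_top", "z_mem_bot", "r_pore", "r_tunnel", "z_tun_bot", "z_tun_top",
    "taper_w", "r_switch_w", "r_free", "sector_halfwidth_rad", "r_gate_region"
  )]
  # the gate senses hydrophobic beads in the channel and queued just above
  # it (pore entrance / gap region)
  out$z_gate_top <- geometry$z_tun_bot
  out
}

cpp_par <- function(params) {
  list(
    dt = params$dt, D = params$D, kBT = params$kBT,
    k_bond = params$k_bond, r_bond = params$r_bond,
    k_anchor = params$k_anchor, k_wall = params$k_wall,
    k_excl = params$k_excl, d_excl = params$d_excl,
    k_head = params$k_head,
    volt = params$membrane_potential,
    gate_dG0 = params$gate_dG0, gate_coupling = params$gate_coupling,
    gate_interval = params$gate_interval_steps
  )
}

# Deterministic per-replicate RNG streams from one master seed.
replicate_seed <- function(seed, length_aa, replicate) {
  (as.numeric(seed) * 2654435761 + length_aa * 97561 + replicate * 131071) %%
    2^48
}

#' Total potential energy of a bead configuration
#'
#' The engine's energy function, exposed for inspection and testing: bond
#' terms, wall repulsion (exit tunnel, ribosome body, membrane slab except
#' through the pore or an open gate), z-tapered transfer free energy inside
#' the bilayer, the membrane-potential term q * Phi(z), and (when the gate
#' is open) the gate bias and occupancy coupling.
#'
#' @param positions An n x 3 matrix of bead positions (nm).
#' @param beads A bead table from [map_to_beads()] (or any data frame with
#'   `hydrophobicity` and `charge`).
#' @param geometry A [cg_geometry()].
#' @param params A [cg_params()].
#' @param gate_open Logical gate state.
#' @return Energy in kcal/mol.
#' @export
potential_energy <- function(positions, beads, geometry, params,
                             gate_open = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == nrow(beads))
  cpp_potential_energy(
    positions, beads$hydrophobicity, beads$charge,
    cpp_geom(geometry), cpp_par(params), gate_open
  )
}

#' Sample the arrest force at one nascent-chain length
#'
#' Grows the chain from `initial_translated` residues at the translation
#' rate (one bead per three residues, bead additions at exact multiples of
#' `3 / translation_rate` seconds), halts translation at `length_aa`,
#' equilibrates briefly, then samples the tension on the anchored
#' C-terminal bead every `force_sample_interval` for
#' `force_sample_duration`. Repeated for `params$replicates` independent
#' replicates with seeds derived deterministically from `params$seed`.
#'
#' @param seq Full protein (construct) sequence; the first `length_aa`
#'   residues are simulated.
#' @param length_aa Arrested nascent-chain length (residues).
#' @param geometry A [cg_geometry()].
#' @param params A [cg_params()].
#' @param baseline `"reference"` (default): report forces relative to the
#'   tension a non-interacting reference chain (zero hydrophobicity and
#'   charge, 20 beads) exerts on the anchor, a single well-converged
#'   constant per geometry/parameter set (cached); this removes the
#'   sequence-independent entropic tension any tethered bead chain
#'   produces, so non-interacting chains read ~0. `"none"`: the raw
#'   anchor tension.
#' @return A one-row tibble: `length_aa`, `mean_force_pN`, `sem_pN`,
#'   `raw_force_pN`, `reference_force_pN`, `replicates`,
#'   `gate_open_fraction`.
#' @export
run_arrested_sampling <- function(seq, length_aa, geometry = cg_geometry(),
                                  params = cg_params(),
                                  baseline = c("reference", "none")) {
  baseline <- match.arg(baseline)
  ch <- aa_chars(seq)
  length_aa <- as.integer(length_aa)
  if (length_aa < params$first_measured_length) {
    abort("length_aa is below first_measured_length")
  }
  if (length_aa > length(ch)) {
    abort("length_aa exceeds the sequence length")
  }
  beads <- map_to_beads(substr(seq, 1, length_aa))
  raw <- cg_raw_tension(
    beads$hydrophobicity * params$transfer_scale, beads$charge,
    length_aa, geometry, params,
    seed_offset = 0
  )
  if (baseline == "reference") {
    ref <- cg_reference_tension(geometry, params)
    mean_force <- raw$mean - ref$mean
    sem <- sqrt(raw$sem^2 + ref$sem^2)
    ref_mean <- ref$mean
  } else {
    mean_force <- raw$mean
    sem <- raw$sem
    ref_mean <- NA_real_
  }
  tibble(
    length_aa = length_aa,
    mean_force_pN = mean_force,
    sem_pN = sem,
    raw_force_pN = raw$mean,
    reference_force_pN = ref_mean,
    replicates = params$replicates,
    gate_open_fraction = raw$gate_open_fraction
  )
}

# Replicate-averaged anchor tension (pN) for explicit bead properties.
cg_raw_tension <- function(h, q, length_aa, geometry, params, seed_offset) {
  n_samples <- floor(params$force_sample_duration / params$force_sample_interval)
  if (n_samples < 2) abort("sampling window shorter than 2 samples")
  n_beads_init <- max(1L, min(
    length(h), as.integer(ceiling(params$initial_translated / 3))
  ))
  growth_interval <- as.integer(round(3 / (params$translation_rate * params$dt)))
  equil_steps <- as.integer(round(params$equilibration / params$dt))
  sample_interval <- as.integer(round(params$force_sample_interval / params$dt))
  per_rep <- vapply(seq_len(params$replicates), function(r) {
    res <- cpp_run_arrested(
      h, q, cpp_geom(geometry), cpp_par(params),
      n_beads_init, growth_interval, equil_steps, sample_interval,
      as.integer(n_samples),
      replicate_seed(params$seed, length_aa, r) + seed_offset
    )
    c(res$mean_force * PN_PER_KCAL_MOL_NM, res$gate_open_fraction)
  }, numeric(2))
  list(
    mean = mean(per_rep[1, ]),
    sem = if (ncol(per_rep) >= 2) {
      stats::sd(per_rep[1, ]) / sqrt(ncol(per_rep))
    } else {
      NA_real_
    },
    gate_open_fraction = mean(per_rep[2, ])
  )
}

# Entropic reference tension of a non-interacting tethered chain: one
# well-converged constant per geometry/dynamics parameter set, memoised.
# 20 beads is long enough that the tension is length-insensitive.
.cg_ref_cache <- new.env(parent = emptyenv())

cg_reference_tension <- function(geometry, params, n_beads = 20L) {
  key <- paste(
    n_beads,
    paste(signif(unlist(geometry[!vapply(geometry, is.character, TRUE)]), 10),
      collapse = ","
    ),
    paste(signif(unlist(params[c(
      "dt", "D", "kBT", "k_bond", "r_bond", "k_anchor", "k_wall",
      "k_excl", "d_excl", "k_head",
      "gate_dG0", "gate_coupling", "gate_interval_steps",
      "initial_translated"
    )]), 10), collapse = ","),
    sep = "|"
  )
  hit <- .cg_ref_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  # converge the constant harder than any single profile point
  ref_params <- params
  ref_params$replicates <- max(params$replicates, 16L)
  ref_params$force_sample_duration <- max(params$force_sample_duration, 1.2)
  # the reference constant does not depend on the growth schedule or the
  # user seed; pin them so the cache is shared across runs
  ref_params$translation_rate <- 500
  ref_params$equilibration <- 0.03
  ref_params$seed <- 1010L
  ref <- cg_raw_tension(
    rep(0, n_beads), rep(0, n_beads),
    3L * n_beads, geometry, ref_params,
    seed_offset = 3e9
  )
  assign(key, ref, envir = .cg_ref_cache)
  ref
}

#' Compute a simulated force profile (CGMD-FP)
#'
#' Runs [run_arrested_sampling()] independently at each length from
#' `first_measured_length` to the sequence length in steps of
#' `length_increment`, and reports forces (pN) against
#' `reported_N = length_aa + shift`. Forces are reported directly rather
#' than converted to f_FL, so profiles are comparable across arrest
#' peptides of different strengths.
#'
#' @param seq Protein (construct) sequence.
#' @param geometry A [cg_geometry()].
#' @param params A [cg_params()].
#' @param shift Integer reporting shift; `NULL` (default) uses
#'   [estimate_tunnel_shift()] on the geometry.
#' @param lengths Optional explicit vector of lengths (aa) overriding the
#'   default grid.
#' @return A `cg_profile`: tibble with `length_aa`, `reported_N`,
#'   `mean_force_pN`, `sem_pN`, `replicates`, `gate_open_fraction`, with
#'   the shift, seed, geometry and params attached as attributes.
#' @export
compute_cgmd_profile <- function(seq, geometry = cg_geometry(),
                                 params = cg_params(), shift = NULL,
                                 lengths = NULL) {
  ch <- aa_chars(seq)
  if (is.null(shift)) shift <- estimate_tunnel_shift(geometry)
  if (is.null(lengths)) {
    lengths <- seq(params$first_measured_length, length(ch),
      by = params$length_increment
    )
  }
  rows <- purrr::map(lengths, function(L) {
    run_arrested_sampling(seq, L, geometry, params)
  }) %>% dplyr::bind_rows()
  out <- rows %>% mutate(reported_N = .data$length_aa + shift, .after = "length_aa")
  attr(out, "shift") <- as.integer(shift)
  attr(out, "seed") <- params$seed
  attr(out, "geometry") <- geometry
  attr(out, "params") <- params
  class(out) <- c("cg_profile", class(out))
  out
}

#' @method tidy cg_profile
#' @export
tidy.cg_profile <- function(x, ...) {
  class(x) <- setdiff(class(x), "cg_profile")
  as_tibble(x)
}

#' @method glance cg_profile
#' @export
glance.cg_profile <- function(x, ...) {
  tibble(
    n_lengths = nrow(x),
    shift = attr(x, "shift"),
    seed = attr(x, "seed"),
    replicates = x$replicates[1],
    peak_force_pN = max(x$mean_force_pN),
    peak_reported_N = x$reported_N[which.max(x$mean_force_pN)]
  )
}

#' Plot a simulated force profile
#'
#' @param object A `cg_profile` from [compute_cgmd_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cg_profile
#' @export
autoplot.cg_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reported_N, y = .data$mean_force_pN)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$mean_force_pN - .data$sem_pN,
        ymax = .data$mean_force_pN + .data$sem_pN
      ),
      colour = "grey40", size = 0.3
    ) +
    ggplot2::labs(
      x = "reported N (residues)", y = "mean force (pN)",
      title = paste0("CGMD force profile (shift ", attr(object, "shift"), ")")
    ) +
    ggplot2::theme_classic()
}

#' Convert a simulated profile to force-profile form for alignment
#'
#' Rescales mean forces to \[0, 1\] (min-max over the profile) so a
#' `cg_profile` can be registered against an experimental f_FL profile with
#' [align_profiles()].
#'
#' @param cgfp A `cg_profile`.
#' @return A [force_profile()] on the reported-N axis.
#' @export
cg_as_force_profile <- function(cgfp) {
  rng <- range(cgfp$mean_force_pN)
  scaled <- if (diff(rng) == 0) {
    rep(0, nrow(cgfp))
  } else {
    (cgfp$mean_force_pN - rng[1]) / diff(rng)
  }
  force_profile(
    tibble(N = cgfp$reported_N, mean_ffl = scaled),
    protein_id = "cgmd", ap_name = "simulated"
  )
}
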