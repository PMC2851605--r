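#' Configuration for a synthetic confounded expression database
#'
#' Describes the generative model behind [simulate_database()]: each
#' instance of class `c`, processed in batch `b` with vehicle `v`, has
#' amplitudes
#' \deqn{A(p) = \delta s_c(p) + \beta_b(p) + \gamma_v(p) + \varepsilon(p)}
#' where `s_c` is +1 on the class's uptag probes, -1 on its downtag probes
#' and 0 elsewhere (class signatures are disjoint across classes so ground
#' truth is unambiguous), `beta_b ~ N(0, batch_sd)` is drawn once per
#' (batch, probe), `gamma_v ~ N(0, vehicle_sd)` once per (vehicle, probe),
#' and `epsilon ~ N(0, noise_sd)` per instance-probe. Batch and vehicle
#' effects are probe-specific and shared within the batch/vehicle, so they
#' perturb rankings — which is what both similarity methods consume.
#'
#' Defaults emulate a strongly batch-confounded retrieval study: 1000
#' probes, 3 therapeutic classes of 40 instances, 4 batches, 2 vehicles,
#' unit class effect against batch effects twice as large
#' (`batch_sd = 2`), moderate vehicle effects and probe noise of 0.5, and
#' 50-probe signature sides.
#'
#' @param m Probe count.
#' @param n_per_class Instances per class.
#' @param classes Number of therapeutic classes `g`.
#' @param batches,vehicles Numbers of batches and vehicles.
#' @param effect_size Class signal amplitude `delta` (>= 0).
#' @param sig_size Probes per class-signature side; `2 * sig_size *
#'   classes <= m`.
#' @param batch_sd,vehicle_sd,noise_sd Standard deviations of the batch,
#'   vehicle and residual components (>= 0; `noise_sd > 0`).
#' @param confounding `"crossed"` assigns batches/vehicles independently
#'   of class (cycling, so every class spans every batch); `"nested"` ties
#'   each class to one batch and one vehicle (complete confounding).
#' @param seed Integer seed; same seed, same database.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 1000, n_per_class = 40, classes = 3,
                       batches = 4, vehicles = 2,
                       effect_size = 1, sig_size = 50,
                       batch_sd = 2, vehicle_sd = 0.5, noise_sd = 0.5,
                       confounding = c("crossed", "nested"), seed = 1) {
  confounding <- match.arg(confounding)
  cfg <- list(m = as.integer(m), n_per_class = as.integer(n_per_class),
              classes = as.integer(classes), batches = as.integer(batches),
              vehicles = as.integer(vehicles), effect_size = effect_size,
              sig_size = as.integer(sig_size), batch_sd = batch_sd,
              vehicle_sd = vehicle_sd, noise_sd = noise_sd,
              confounding = confounding, seed = as.integer(seed))
  if (2 * cfg$sig_size * cfg$classes > cfg$m) {
    stop("class signatures would overlap: need 2 * sig_size * classes <= m",
         call. = FALSE)
  }
  if (cfg$effect_size < 0 || cfg$batch_sd < 0 || cfg$vehicle_sd < 0) {
    stop("effect_size and nuisance sds must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$m < 2 || cfg$n_per_class < 1 || cfg$classes < 1 ||
      cfg$batches < 1 || cfg$vehicles < 1) {
    stop("dimensions must be positive (m >= 2)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic confounded expression database
#'
#' Draws a probes-by-instances amplitude table plus instance metadata from
#' the model described in [sim_config()]. Deterministic given the config's
#' seed; the same config yields a byte-identical database.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `expression` (tibble: `probe_id` plus one
#'   column per instance), `metadata` (tibble: `instance_id`, `name`,
#'   `class`, `subclass`, `vehicle`, `batch`, `mol`) and `signatures`
#'   (tibble of the planted class signature probes: `class`, `direction`,
#'   `probe_id`).
#' @examples
#' db <- simulate_database(sim_config(m = 100, n_per_class = 4,
#'                                    classes = 2, sig_size = 10, seed = 7))
#' dim(db$expression)
#' db$metadata
#' @export
simulate_database <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  n <- cfg$n_per_class * cfg$classes
  probe_ids <- sprintf("p%04d", seq_len(cfg$m))
  inst_ids <- sprintf("inst%03d", seq_len(n))
  class_of <- rep(seq_len(cfg$classes), each = cfg$n_per_class)
  within <- stats::ave(seq_len(n), class_of, FUN = seq_along)

  if (cfg$confounding == "crossed") {
    # cycle within class so every class spans every batch and vehicle;
    # vehicle varies on the slower cycle so (batch, vehicle) combinations
    # are crossed with each other and with class
    batch_of <- ((within - 1L) %% cfg$batches) + 1L
    vehicle_of <- (((within - 1L) %/% cfg$batches) %% cfg$vehicles) + 1L
  } else {
    batch_of <- ((class_of - 1L) %% cfg$batches) + 1L
    vehicle_of <- ((class_of - 1L) %% cfg$vehicles) + 1L
  }

  # disjoint class signatures: class c owns probes in one contiguous block
  sig <- matrix(0, cfg$m, cfg$classes)
  sig_tbl <- purrr::map_dfr(seq_len(cfg$classes), function(c) {
    up <- ((c - 1L) * 2L * cfg$sig_size + 1L):((c - 1L) * 2L * cfg$sig_size + cfg$sig_size)
    down <- up + cfg$sig_size
    sig[up, c] <<- 1
    sig[down, c] <<- -1
    tibble::tibble(class = sprintf("class%02d", c),
                   direction = rep(c("up", "down"), each = cfg$sig_size),
                   probe_id = probe_ids[c(up, down)])
  })

  amp <- withr::with_seed(cfg$seed, {
    beta <- matrix(stats::rnorm(cfg$m * cfg$batches, 0, cfg$batch_sd),
                   cfg$m, cfg$batches)
    gamma <- matrix(stats::rnorm(cfg$m * cfg$vehicles, 0, cfg$vehicle_sd),
                    cfg$m, cfg$vehicles)
    eps <- matrix(stats::rnorm(cfg$m * n, 0, cfg$noise_sd), cfg$m, n)
    cfg$effect_size * sig[, class_of, drop = FALSE] +
      beta[, batch_of, drop = FALSE] + gamma[, vehicle_of, drop = FALSE] + eps
  })
  colnames(amp) <- inst_ids

  expression <- dplyr::bind_cols(
    tibble::tibble(probe_id = probe_ids),
    tibble::as_tibble(as.data.frame(amp, optional = TRUE))
  )
  metadata <- tibble::tibble(
    instance_id = inst_ids,
    name = sprintf("cmpd_%02d_%02d", class_of, within),
    class = sprintf("class%02d", class_of),
    subclass = sprintf("class%02d", class_of),
    vehicle = vehicle_labels(cfg$vehicles)[vehicle_of],
    batch = sprintf("batch%02d", batch_of),
    mol = 1e-05
  )
  list(expression = expression, metadata = metadata, signatures = sig_tbl)
}

vehicle_labels <- function(v) {
  solvents <- c("water", "DMSO", "EtOH", "MeOH")
  if (v <= length(solvents)) solvents[seq_len(v)] else sprintf("veh%02d", seq_len(v))
}
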