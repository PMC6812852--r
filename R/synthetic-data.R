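#' Stimulation protocols
#'
#' The constant-frequency protocol of a recording session: which motoneuron is
#' driven (slow SETi or fast FETi), at which frequencies, for how long, and at
#' what sampling rate. The canonical frequency lists are 1, 7, 10, 12.5, 15,
#' 20, 25, 30, 40 and 50 Hz for SETi and 1, 10, 20, 30 and 50 Hz for FETi;
#' 1 Hz with a 1 s epoch is the single twitch. The default uses 1 s
#' stimulation plus 1 s relaxation per frequency; longer epochs are a matter
#' of configuration.
#'
#' @param neuron_label `"SETi"` or `"FETi"`.
#' @param freqs Frequencies in Hz; must be non-empty and should include the
#'   1 Hz single twitch when fitting workflows will run.
#' @param stim_duration Stimulation epoch per frequency in seconds.
#' @param relax_time Post-stimulus relaxation window in seconds.
#' @param dt Sampling step in seconds (default 5 kHz).
#' @return An object of class `protocol`.
#' @export
protocol <- function(neuron_label = c("SETi", "FETi"), freqs = NULL,
                     stim_duration = 1, relax_time = 1, dt = 0.0002) {
  neuron_label <- match.arg(neuron_label)
  if (is.null(freqs)) {
    freqs <- if (neuron_label == "SETi") {
      c(1, 7, 10, 12.5, 15, 20, 25, 30, 40, 50)
    } else {
      c(1, 10, 20, 30, 50)
    }
  }
  if (!length(freqs)) stop("freqs must be non-empty", call. = FALSE)
  structure(list(neuron_label = neuron_label, freqs = sort(unique(freqs)),
                 stim_duration = stim_duration, relax_time = relax_time,
                 dt = dt), class = "protocol")
}

#' @rdname protocol
#' @export
seti_protocol <- function(stim_duration = 1, relax_time = 1, dt = 0.0002) {
  protocol("SETi", stim_duration = stim_duration, relax_time = relax_time,
           dt = dt)
}

#' @rdname protocol
#' @export
feti_protocol <- function(stim_duration = 1, relax_time = 1, dt = 0.0002) {
  protocol("FETi", stim_duration = stim_duration, relax_time = relax_time,
           dt = dt)
}

#' Generate a synthetic per-animal dataset
#'
#' Emulates the structure of a per-animal recording session: one
#' constant-frequency force trace per protocol frequency, sampled at 5 kHz,
#' normalised to the session ("animal") maximum, with optional additive
#' Gaussian noise whose standard deviation is a fraction of that maximum. The
#' noiseless traces are kept alongside, and the whole dataset is reproducible
#' from (model, parameters, protocol, noise level, seed). The noise model is
#' i.i.d. Gaussian, a documented stand-in: real transducer recordings are
#' unfiltered and their noise is not characterised here.
#'
#' @param model Model name (see [simulate_muscle()]).
#' @param params Matching parameter object.
#' @param proto A [protocol()].
#' @param noise_sd Noise standard deviation as a fraction of the per-animal
#'   maximum (>= 0).
#' @param seed Integer seed for the noise draws.
#' @param config Optional [sim_config()]; defaults to the protocol's `dt` with
#'   its `relax_time`.
#' @param ... Passed to the simulator.
#' @return An object of class `muscle_dataset`: the protocol, generator
#'   provenance, and per-frequency `force_trace`s (`traces` noisy — equal to
#'   clean when `noise_sd = 0` — and `traces_clean`).
#' @export
generate_dataset <- function(model, params, proto = seti_protocol(),
                             noise_sd = 0, seed = 1,
                             config = NULL, ...) {
  stopifnot(inherits(proto, "protocol"))
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (is.null(config)) {
    config <- sim_config(dt = proto$dt, relax_time = proto$relax_time)
  }
  clean <- purrr::map(proto$freqs, function(f) {
    tr <- simulate_muscle(model, params, constant_train(f, proto$stim_duration),
                          config, ...)
    m <- trace_meta(tr)
    m$freq <- f
    m$stim_duration <- proto$stim_duration
    m$neuron <- proto$neuron_label
    attr(tr, "meta") <- m
    tr
  })
  names(clean) <- sprintf("%gHz", proto$freqs)
  peak <- max(vapply(clean, function(tr) max(tr$force), numeric(1)))
  if (peak <= 0) stop("generator produced no positive force", call. = FALSE)
  clean <- purrr::map(clean, function(tr) {
    m <- trace_meta(tr)
    m$normalisation <- list(reference = "per_animal_max", scale = peak)
    new_force_trace(tr$time, tr$force / peak, trace_dt(tr), m)
  })
  noisy <- clean
  if (noise_sd > 0) {
    noisy <- with_seed(seed, purrr::map(clean, function(tr) {
      new_force_trace(tr$time, tr$force + rnorm(nrow(tr), 0, noise_sd),
                      trace_dt(tr), trace_meta(tr))
    }))
  }
  structure(list(protocol = proto, generator_model = model,
                 generator_params = params, noise_sd = noise_sd, seed = seed,
                 traces = noisy, traces_clean = clean),
            class = "muscle_dataset")
}

#' @export
print.muscle_dataset <- function(x, ...) {
  cat(sprintf("<muscle_dataset> %s, %d frequencies (%s Hz), noise_sd %g, seed %d\n",
              x$protocol$neuron_label, length(x$protocol$freqs),
              paste(x$protocol$freqs, collapse = ", "), x$noise_sd, x$seed))
  invisible(x)
}

#' Write / read a synthetic dataset directory
#'
#' One directory per synthetic animal: a `metadata.json` with the protocol and
#' generator provenance, plus one two-column delimited trace file per
#' frequency (and the noiseless counterparts under `clean_`). The reader
#' accepts the same layout for exported real recordings: `metadata.json` may
#' then omit the generator fields.
#'
#' @param dataset A `muscle_dataset`.
#' @param path Directory to create.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "muscle_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  gp <- dataset$generator_params
  meta <- list(
    protocol = unclass(dataset$protocol),
    generator_model = dataset$generator_model,
    generator_params = if (is.null(gp)) NULL else
      unclass(gp)[setdiff(names(unclass(gp)), "tau_deact")],
    noise_sd = dataset$noise_sd,
    seed = dataset$seed
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(dataset$traces)) {
    write_force_trace(dataset$traces[[nm]],
                      file.path(path, sprintf("force_%s.tsv", nm)))
  }
  for (nm in names(dataset$traces_clean)) {
    write_force_trace(dataset$traces_clean[[nm]],
                      file.path(path, sprintf("clean_force_%s.tsv", nm)))
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mpath <- file.path(path, "metadata.json")
  if (!file.exists(mpath)) {
    stop(sprintf("no metadata.json in '%s'", path), call. = FALSE)
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(meta$protocol)) {
    stop("malformed metadata.json: missing 'protocol' field", call. = FALSE)
  }
  proto <- protocol(meta$protocol$neuron_label, meta$protocol$freqs,
                    meta$protocol$stim_duration, meta$protocol$relax_time,
                    meta$protocol$dt)
  read_group <- function(prefix) {
    out <- list()
    for (f in proto$freqs) {
      fp <- file.path(path, sprintf("%sforce_%gHz.tsv", prefix, f))
      if (!file.exists(fp)) next
      tr <- read_force_trace(fp)
      m <- trace_meta(tr)
      m$freq <- f
      m$stim_duration <- proto$stim_duration
      m$neuron <- proto$neuron_label
      attr(tr, "meta") <- m
      out[[sprintf("%gHz", f)]] <- tr
    }
    out
  }
  traces <- read_group("")
  if (!length(traces)) stop("no trace files found", call. = FALSE)
  clean <- read_group("clean_")
  gp <- NULL
  if (!is.null(meta$generator_model) && !is.null(meta$generator_params)) {
    gp <- tryCatch(
      do.call(paste0(params_class_for(meta$generator_model)),
              as.list(meta$generator_params)),
      error = function(e) NULL)
  }
  structure(list(protocol = proto,
                 generator_model = meta$generator_model,
                 generator_params = gp,
                 noise_sd = if (is.null(meta$noise_sd)) NA_real_ else meta$noise_sd,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                 traces = traces,
                 traces_clean = if (length(clean)) clean else NULL),
            class = "muscle_dataset")
}
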