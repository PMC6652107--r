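#' Study design of the longitudinal hepatectomy cohort
#'
#' Encodes the sampling structure of the animal study the synthetic
#' generator emulates: a cross-sectional pool of untreated control
#' mice (assigned day 0), and post-hepatectomy (phx) and sham-operated
#' groups sampled at days 4, 8, 14, and 21. The default group sizes
#' are the study's: 10 untreated; 5/4/4/4 phx; 3/3/3/6 sham.
#'
#' @param phx_n,sham_n Animals per day (days 4, 8, 14, 21) in the phx
#'   and sham groups.
#' @param untreated_n Untreated control pool size.
#' @param days Sampling days for the operated groups.
#' @param observables Observables recorded per animal; default all
#'   four.
#' @return A list of class `study_design` with a `cells` data frame
#'   (`group`, `day`, `n`) and the `observables` vector.
#' @export
study_design <- function(phx_n = c(5, 4, 4, 4), sham_n = c(3, 3, 3, 6),
                         untreated_n = 10, days = c(4, 8, 14, 21),
                         observables = .OBSERVABLES) {
  if (length(phx_n) != length(days) || length(sham_n) != length(days)) {
    stop("phx_n and sham_n must give one group size per sampling day",
         call. = FALSE)
  }
  sizes <- c(untreated_n, phx_n, sham_n)
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    stop("all group sizes must be integers >= 1", call. = FALSE)
  }
  unknown <- setdiff(observables, .OBSERVABLES)
  if (length(unknown)) {
    stop("unknown observable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cells <- rbind(
    data.frame(group = "untreated", day = 0, n = as.integer(untreated_n)),
    data.frame(group = "phx", day = days, n = as.integer(phx_n)),
    data.frame(group = "sham", day = days, n = as.integer(sham_n))
  )
  structure(list(cells = cells, observables = observables),
            class = "study_design")
}

#' Per-animal measurement noise model
#'
#' Additive Gaussian noise on the measurement scale with standard
#' deviation proportional to the cell's true mean (SD = CV x mean),
#' independent across animals, truncated at zero because all measured
#' quantities are nonnegative. A CV of 0 yields exact values.
#'
#' @param cv A single coefficient of variation applied to every
#'   observable, or a named vector with one CV per observable.
#' @return A named numeric vector of class `noise_model`.
#' @export
noise_model <- function(cv = 0.15) {
  if (length(cv) == 1L && is.null(names(cv))) {
    cv <- stats::setNames(rep(as.numeric(cv), length(.OBSERVABLES)),
                          .OBSERVABLES)
  }
  if (!all(.OBSERVABLES %in% names(cv))) {
    stop("noise model needs a CV for each observable", call. = FALSE)
  }
  cv <- cv[.OBSERVABLES]
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("CV values must be finite and >= 0", call. = FALSE)
  }
  structure(cv, class = "noise_model")
}

#' Generate a synthetic measurement cohort
#'
#' Simulates the post-hepatectomy time course from `params_true`, maps
#' it to measurement scales, and emits one record per animal and
#' observable. Post-hepatectomy animals receive the mapped curve value
#' at their sampling day; sham-operated and untreated animals receive
#' the mapped homeostatic values, reflecting the finding that sham
#' surgery does not alter the measured quantities. Per-animal noise
#' follows the [noise_model()]. The generator is deterministic given
#' `seed` and restores the caller's RNG state.
#'
#' @param params_true Generating `model_parameters`.
#' @param mapping An `observable_mapping`.
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param step Integration step in days; sampling days must lie on the
#'   grid.
#' @return A data frame of class `measurement_dataset` with columns
#'   `group`, `day`, `animal`, `observable`, `value`.
#' @export
generate_cohort <- function(params_true, mapping = observable_mapping(),
                            design = study_design(), noise = noise_model(),
                            seed = 1L, step = 1 / 24) {
  validate_parameters(params_true)
  if (!inherits(design, "study_design")) {
    stop("design must come from study_design()", call. = FALSE)
  }
  noise <- noise_model(unclass(noise))
  cells <- design$cells
  phx_days <- cells$day[cells$group == "phx"]
  duration <- max(ceiling(max(phx_days)), 1)
  sim <- simulate_phx(params_true, duration = duration, step = step)
  on_grid <- abs(phx_days / step - round(phx_days / step)) < 1e-9
  if (!all(on_grid)) {
    stop("sampling day not on the simulation grid: ",
         paste(phx_days[!on_grid], collapse = ", "), call. = FALSE)
  }
  phx_at <- sample_at_days(sim$curves, sort(unique(phx_days)))
  hom <- homeostatic_observables()

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  rows <- vector("list", nrow(cells) * length(design$observables))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    grp <- cells$group[i]; day <- cells$day[i]; n <- cells$n[i]
    for (obs in design$observables) {
      true_model <- if (grp == "phx") {
        phx_at[[obs]][match(day, phx_at$day)]
      } else {
        hom[[obs]]
      }
      true_meas <- map_values(true_model, obs, mapping)
      sdev <- unclass(noise)[[obs]] * abs(true_meas)
      vals <- if (sdev > 0) {
        pmax(0, stats::rnorm(n, mean = true_meas, sd = sdev))
      } else {
        rep(true_meas, n)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        group = grp, day = day,
        animal = sprintf("%s_d%g_%02d", grp, day, seq_len(n)),
        observable = obs, value = vals
      )
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  class(out) <- c("measurement_dataset", "data.frame")
  out
}

#' Summarize a measurement dataset as mean and SD per cell
#'
#' Computes the sample mean and sample standard deviation (n - 1
#' denominator) for each (group, day, observable) cell. Cells with a
#' single animal report `NA` for the SD rather than zero, since the
#' sample SD is undefined at n = 1.
#'
#' @param dataset A per-animal dataset with columns `group`, `day`,
#'   `observable`, `value`.
#' @return A data frame with columns `group`, `day`, `observable`,
#'   `n`, `mean`, `sd`.
#' @export
summarize_dataset <- function(dataset) {
  need <- c("group", "day", "observable", "value")
  if (!is.data.frame(dataset) || nrow(dataset) == 0L ||
      !all(need %in% names(dataset))) {
    stop("dataset must be non-empty with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  key <- interaction(dataset$group, dataset$day, dataset$observable,
                     drop = TRUE)
  pieces <- lapply(split(dataset, key), function(d) {
    data.frame(group = d$group[1L], day = d$day[1L],
               observable = d$observable[1L], n = nrow(d),
               mean = mean(d$value),
               sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$group, out$day, out$observable), ]
  rownames(out) <- NULL
  out
}

.GROUPS <- c("untreated", "sham", "phx")

#' Read or write a measurement dataset as CSV
#'
#' The CSV dialect has one row per animal-observable with columns
#' `group` (untreated/sham/phx), `day` (number), `observable`
#' (volume/total_macrophages/kupffer/angiogenesis), `value` (number),
#' and optionally `animal`. Malformed rows are reported by row number.
#'
#' @param path File path.
#' @param dataset A `measurement_dataset` (for writing).
#' @return `read_dataset_csv()` returns a `measurement_dataset`;
#'   `write_dataset_csv()` returns `path` invisibly.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "day", "observable", "value")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(d$group %in% .GROUPS) | !(d$observable %in% .OBSERVABLES) |
                 !is.finite(suppressWarnings(as.numeric(d$value))) |
                 !is.finite(suppressWarnings(as.numeric(d$day))))
  if (length(bad)) {
    stop("malformed dataset row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         " (unknown group/observable or non-numeric day/value)",
         call. = FALSE)
  }
  d$day <- as.numeric(d$day)
  d$value <- as.numeric(d$value)
  if (!"animal" %in% names(d)) {
    d$animal <- sprintf("row_%04d", seq_len(nrow(d)))
  }
  d <- d[, c("group", "day", "animal", "observable", "value")]
  class(d) <- c("measurement_dataset", "data.frame")
  d
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
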