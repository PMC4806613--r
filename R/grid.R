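#' Run the stress-level by scenario experiment grid
#'
#' Sweeps population-mean stress over `grid$s_mean_values`, crossed with
#' the listed perturbation scenarios, with `grid$replicates` Monte Carlo
#' replicates per cell. Seeds derive deterministically from
#' `(base_seed, s_mean, replicate)` — deliberately *not* from the scenario
#' — so matched replicates of different scenarios run under common random
#' numbers and share their trajectory until the perturbation starts.
#'
#' @param grid A [grid_spec()].
#' @param cfg A [model_config()]; its `s_mean` is overridden cell by cell.
#' @param keep_yearly If `TRUE` (default) keep per-cell yearly mean
#'   trajectories and breeder statistics.
#' @return An object of class `"stress_grid"`: a list with tibbles
#'   \describe{
#'     \item{cells}{one row per (s_mean, scenario): `mean_final_size`,
#'       `sd_final_size`, `extinct_frac`, `rel_halfwidth`, `converged`.}
#'     \item{finals}{one row per replicate: `final_size` (mean population
#'       over the last simulated year) and `extinct`.}
#'     \item{yearly}{per (s_mean, scenario, year): mean population size at
#'       the peak month across replicates, and pooled breeder condition /
#'       age summaries (`NA` when nothing bred).}
#'   }
#' @examples
#' g <- grid_spec(s_mean_values = c(0, 50), replicates = 2)
#' cfg <- model_config(sim_years = 3, init_pop_size = 50)
#' run_grid(g, cfg)$cells
#' @export
run_grid <- function(grid, cfg, keep_yearly = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cfg, "stress_config"))
  cells <- list(); finals <- list(); yearly <- list()
  k <- 0L
  for (sc in grid$scenarios) {
    lab <- scenario_label(sc)
    for (sm in grid$s_mean_values) {
      cfg_cell <- cfg
      cfg_cell$s_mean <- sm
      reps <- lapply(seq_len(grid$replicates), function(r) {
        run_simulation(cfg_cell, sc,
                       seed = derive_seed(grid$base_seed, sm, r))
      })
      fin <- vapply(reps, final_size, numeric(1))
      ext <- vapply(reps, function(x) x$extinct, logical(1))
      conv <- if (grid$replicates >= 2L) convergence_check(fin) else
        tibble::tibble(converged = NA, rel_halfwidth = NA_real_)
      k <- k + 1L
      cells[[k]] <- tibble::tibble(
        s_mean = sm, scenario = lab, n_reps = grid$replicates,
        mean_final_size = mean(fin), sd_final_size = stats::sd(fin),
        extinct_frac = mean(ext),
        rel_halfwidth = conv$rel_halfwidth[1], converged = conv$converged[1])
      finals[[k]] <- tibble::tibble(
        s_mean = sm, scenario = lab, replicate = seq_len(grid$replicates),
        final_size = fin, extinct = ext)
      if (keep_yearly) {
        ys <- dplyr::bind_rows(lapply(seq_along(reps), function(r) {
          dplyr::mutate(yearly_summaries(reps[[r]]), replicate = r)
        }))
        yearly[[k]] <- ys |>
          dplyr::group_by(.data$year) |>
          dplyr::summarise(
            mean_pop_size = mean(.data$pop_size),
            mean_breeder_condition = pooled_mean(.data$mean_breeder_condition,
                                                 .data$n_breeders),
            mean_breeder_age = pooled_mean(.data$mean_breeder_age,
                                           .data$n_breeders),
            n_breeders = sum(.data$n_breeders), .groups = "drop") |>
          dplyr::mutate(s_mean = sm, scenario = lab, .before = 1)
      }
    }
  }
  structure(
    list(cells = dplyr::bind_rows(cells), finals = dplyr::bind_rows(finals),
         yearly = if (keep_yearly) dplyr::bind_rows(yearly) else NULL,
         grid = grid, cfg = cfg),
    class = "stress_grid")
}

# breeder-weighted mean of per-replicate means; NA when nothing bred
pooled_mean <- function(m, n) {
  ok <- n > 0 & !is.na(m)
  if (!any(ok)) return(NA_real_)
  sum(m[ok] * n[ok]) / sum(n[ok])
}

#' Mean population size over the final simulated year
#' @param run A `"stress_run"`.
#' @return Mean of the last 12 monthly sizes.
#' @export
final_size <- function(run) mean(tail(run$monthly$pop_size, 12L))

# deterministic replicate seed; scenario-independent so matched replicates
# of different scenarios share common random numbers
derive_seed <- function(base_seed, s_mean, replicate) {
  as.integer((as.double(base_seed) * 7919 +
                round(s_mean * 100) * 104729 +
                as.double(replicate) * 15485863) %% 2147483629)
}

#' Monte Carlo convergence diagnostic
#'
#' Summarises how tightly the replicate final population sizes pin down
#' their mean. The default statistic is the relative 95% confidence
#' half-width, `1.96 * SE(mean) / mean`, declared converged at or below
#' `tol`; `method = "running"` instead reports the maximum relative
#' deviation of the running mean (from the second replicate on) from the
#' full-replication mean. A cell in which every replicate went extinct
#' (mean 0) is converged by convention.
#'
#' @param final_sizes Numeric vector of per-replicate final sizes
#'   (length >= 2).
#' @param tol Relative tolerance (default 0.05).
#' @param method `"ci"` (default) or `"running"`.
#' @return One-row tibble: `converged`, `rel_halfwidth`, `n`, `mean`.
#' @examples
#' convergence_check(c(100, 200))
#' @export
convergence_check <- function(final_sizes, tol = 0.05,
                              method = c("ci", "running")) {
  method <- match.arg(method)
  n <- length(final_sizes)
  if (n < 2L) abort("convergence_check() needs at least 2 replicates")
  m <- mean(final_sizes)
  rh <- if (m == 0) 0 else if (method == "ci") {
    1.96 * stats::sd(final_sizes) / sqrt(n) / m
  } else {
    running <- cumsum(final_sizes) / seq_len(n)
    max(abs(running[-1] - m)) / m
  }
  tibble::tibble(converged = rh <= tol, rel_halfwidth = rh, n = n, mean = m)
}

#' Segment the stress axis into three emergent groups
#'
#' Partitions the sorted stress axis into three contiguous segments that
#' minimise the total within-segment variance of `log(final size + 1)`,
#' by exhaustive search over the two cut points. This recovers the three
#' qualitative regimes a stress-stratified population grid exhibits: large
#' low-stress populations, an intermediate band, and a collapsed
#' high-stress band. Objective ties are broken deterministically toward
#' cuts at stress 6/7 and 35/36 (the canonical boundaries); a tie-break is
#' flagged in the output attribute `"tie_broken"`.
#'
#' @param data A data frame with columns `s_mean` (sorted, >= 5 distinct
#'   values) and `final_size`.
#' @return A tibble with one row per group, highest-stress group first
#'   (group 1, as conventionally numbered): `group`, `s_lo`, `s_hi`,
#'   `mean_size`, `n`. Attribute `"cuts"` holds the two boundary pairs.
#' @examples
#' d <- tibble::tibble(s_mean = 0:50,
#'                     final_size = c(rep(1000, 7), rep(400, 29), rep(20, 15)))
#' classify_groups(d)
#' @export
classify_groups <- function(data) {
  if (!all(c("s_mean", "final_size") %in% names(data))) {
    abort("classify_groups() needs columns s_mean and final_size")
  }
  s <- data$s_mean
  if (is.unsorted(s, strictly = TRUE)) {
    abort("s_mean must be sorted and strictly increasing")
  }
  n <- length(s)
  if (n < 5L) abort("classify_groups() needs at least 5 grid points")
  y <- log(data$final_size + 1)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  sse <- function(i, j) { # within-SSE of y[i..j]
    s1 <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s1^2 / (j - i + 1)
  }
  best <- Inf; best_cut <- NULL; tie <- FALSE
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      obj <- sse(1, i) + sse(i + 1, j) + sse(j + 1, n)
      if (obj < best - 1e-9) {
        best <- obj; best_cut <- c(i, j); tie <- FALSE
      } else if (abs(obj - best) <= 1e-9) {
        # prefer the objective-equal cuts nearest the canonical boundaries
        d_new <- abs(s[i] - 6.5) + abs(s[j] - 35.5)
        d_old <- abs(s[best_cut[1]] - 6.5) + abs(s[best_cut[2]] - 35.5)
        tie <- TRUE
        if (d_new < d_old) best_cut <- c(i, j)
      }
    }
  }
  i <- best_cut[1]; j <- best_cut[2]
  segs <- list(1:i, (i + 1):j, (j + 1):n)   # low, mid, high stress
  out <- tibble::tibble(
    group = c(3L, 2L, 1L),
    s_lo = c(s[1], s[i + 1], s[j + 1]),
    s_hi = c(s[i], s[j], s[n]),
    mean_size = vapply(segs, function(ix) mean(data$final_size[ix]),
                       numeric(1)),
    n = lengths(segs)
  )[3:1, ]
  structure(out, cuts = list(low = c(s[i], s[i + 1]),
                             high = c(s[j], s[j + 1])),
            tie_broken = tie)
}

#' Years until a perturbed population matches its control
#'
#' Scans matched yearly population series for the smallest lag `k >= 1`
#' such that from year `start_year + k` onward the perturbed series stays
#' within a relative tolerance band around the control:
#' `|perturbed - control| / max(control, 1) <= tol` for every remaining
#' year. Returns `NA` (not recovered) when no such lag exists within the
#' series — including when the band is never re-entered before the series
#' ends.
#'
#' @param perturbed,control Equal-length yearly mean population sizes;
#'   element `i` is year `i - 1` (0-based calendar years, matching
#'   [yearly_summaries()]).
#' @param start_year Year the perturbation began (0-based).
#' @param tol Relative tolerance (default 0.05, mirroring the Monte Carlo
#'   convergence tolerance).
#' @return Integer number of years, or `NA_integer_` if not recovered.
#' @examples
#' ctrl <- rep(100, 30)
#' pert <- c(rep(100, 10), rep(70, 10), rep(100, 10))
#' recovery_time(pert, ctrl, start_year = 9)
#' @export
recovery_time <- function(perturbed, control, start_year, tol = 0.05) {
  if (length(perturbed) != length(control)) {
    abort("perturbed and control series must have equal length")
  }
  if (tol <= 0) abort("tol must be > 0")
  n <- length(control)
  dev <- abs(perturbed - control) / pmax(control, 1)
  ok_from <- rev(cumprod(rev(dev <= tol))) == 1  # TRUE where all later ok
  for (k in seq_len(n)) {
    y <- start_year + k        # 0-based year; series index y + 1
    if (y + 1L > n) break      # nothing left to check: never recovered
    if (ok_from[y + 1L]) return(k)
  }
  NA_integer_
}

#' @export
print.stress_grid <- function(x, ...) {
  cat(sprintf("<stress_grid> %d stress level(s) x %d scenario(s) x %d reps\n",
              length(x$grid$s_mean_values), length(x$grid$scenarios),
              x$grid$replicates))
  print(x$cells)
  invisible(x)
}
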