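# Parameter-grid database over the four synaptic properties and selection
# of the optimal balanced "wild-type" networks.

#' Parameter grid specification
#'
#' Defaults reproduce the study grid: 20 linearly spaced connectivity
#' levels from 5 to 100%, 20 linearly spaced g_max_ampa values from 2.78 to
#' 55.56 nS (step 2.78), 20 log-spaced relative-inhibition values from 0.01
#' to 100, and 20 log-spaced gamma_ltd values from 0.1 to 10 (consecutive
#' ratio 10^(2/19) ~ 1.274). The full factorial is 160,000 combinations;
#' with the 6 pattern-set sizes that is 960,000 database conditions, each
#' aggregating 3 connectivity profiles x 10 memory sets (x 6 sizes = 180
#' simulations per combination). Pass a smaller `n` per axis (e.g. 5) for a
#' desk-scale sweep.
#'
#' @param n_connectivity,n_g,n_inhibition,n_gamma Points per axis.
#' @param connectivity,g_max_ampa,relative_inhibition,gamma_ltd Explicit
#'   axis values overriding the defaults (e.g. `connectivity = 0.5` to
#'   constrain that axis).
#' @param sizes Pattern-set sizes stored in the database.
#' @return Object of class `grid_spec` holding the four axis value vectors
#'   and `sizes`.
#' @export
grid_spec <- function(n_connectivity = 20, n_g = 20, n_inhibition = 20,
                      n_gamma = 20, connectivity = NULL, g_max_ampa = NULL,
                      relative_inhibition = NULL, gamma_ltd = NULL,
                      sizes = c(5, 10, 15, 20, 25, 30)) {
  spec <- list(
    connectivity = if (is.null(connectivity)) {
      seq(0.05, 1, length.out = n_connectivity)
    } else connectivity,
    g_max_ampa = if (is.null(g_max_ampa)) {
      seq(2.78, 55.56, length.out = n_g)
    } else g_max_ampa,
    relative_inhibition = if (is.null(relative_inhibition)) {
      10^seq(log10(0.01), log10(100), length.out = n_inhibition)
    } else relative_inhibition,
    gamma_ltd = if (is.null(gamma_ltd)) {
      10^seq(log10(0.1), log10(10), length.out = n_gamma)
    } else gamma_ltd,
    sizes = sizes
  )
  stopifnot(all(spec$connectivity > 0), all(spec$connectivity <= 1),
            all(spec$relative_inhibition >= 0), all(spec$gamma_ltd > 0),
            all(spec$sizes >= 1))
  class(spec) <- "grid_spec"
  spec
}

#' Enumerate the full factorial parameter grid
#'
#' @param spec A [grid_spec()].
#' @return Data frame with one row per combination and columns
#'   `connectivity`, `g_max_ampa`, `gamma_ltd`, `relative_inhibition`
#'   (deterministic enumeration order).
#' @export
build_grid <- function(spec) {
  g <- expand.grid(relative_inhibition = spec$relative_inhibition,
                   gamma_ltd = spec$gamma_ltd,
                   g_max_ampa = spec$g_max_ampa,
                   connectivity = spec$connectivity,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("connectivity", "g_max_ampa", "gamma_ltd", "relative_inhibition")]
}

#' Run the parameter sweep with the threshold-table fast path
#'
#' For every grid combination and pattern-set size, error rates are
#' aggregated over `n_profiles` connectivity profiles x `n_sets` memory
#' sets. Expensive intermediates (adjacency, patterns, coactivation counts,
#' and the gamma_ltd-dependent normalized weight drive) are shared across
#' the g_max_ampa and inhibition axes, which changes nothing numerically:
#' every record equals an independent [evaluate_config()] call with the
#' same seeds.
#'
#' @param spec A [grid_spec()].
#' @param table Threshold table; must cover the largest gGABA on the grid.
#' @param n_profiles,n_sets Run-grid dimensions (study design: 3 and 10).
#' @param seed Base seed; all run seeds derive from it.
#' @param checkpoint Optional CSV path; completed connectivity blocks are
#'   appended so an interrupted sweep can be resumed.
#' @param resume If `TRUE` and `checkpoint` exists, finished connectivity
#'   blocks are loaded instead of recomputed.
#' @param progress Print per-block timing.
#' @return Data frame of class `sweep_db`: one row per (combination, size)
#'   with columns `connectivity`, `g_max_ampa`, `gamma_ltd`,
#'   `relative_inhibition`, `n_patterns`, `sep_err`, `comp_err`, `max_err`,
#'   `sep_sem`, `comp_sem`.
#' @export
run_sweep <- function(spec, table, n_profiles = 3, n_sets = 10, seed = 1,
                      checkpoint = NULL, resume = FALSE, progress = FALSE) {
  g_i_needed <- max(spec$g_max_ampa) * 10 * max(spec$connectivity) *
    max(spec$relative_inhibition)
  if (g_i_needed > max(table$gI) * (1 + 1e-9)) {
    stop("threshold table covers gI up to ", format(max(table$gI)),
         " nS but the grid requires ", format(g_i_needed),
         " nS; rebuild the table with larger g_i_max")
  }
  done <- NULL
  if (resume && !is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
  }
  blocks <- list()
  for (conn in spec$connectivity) {
    if (!is.null(done) && any(abs(done$connectivity - conn) < 1e-12)) {
      blocks[[length(blocks) + 1L]] <-
        done[abs(done$connectivity - conn) < 1e-12, ]
      next
    }
    t0 <- proc.time()[3]
    blk <- .sweep_block(spec, conn, table, n_profiles, n_sets, seed)
    blocks[[length(blocks) + 1L]] <- blk
    if (!is.null(checkpoint)) {
      new_file <- !file.exists(checkpoint)
      utils::write.table(blk, checkpoint, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file)
    }
    if (progress) {
      message(sprintf("connectivity %.3f done in %.1f s", conn,
                      proc.time()[3] - t0))
    }
  }
  db <- do.call(rbind, blocks)
  rownames(db) <- NULL
  class(db) <- c("sweep_db", "data.frame")
  db
}

# One connectivity level: all (gamma, g, inhibition) x sizes records.
.sweep_block <- function(spec, conn, table, n_profiles, n_sets, seed) {
  base_cfg <- network_config(connectivity_level = conn)
  n <- base_cfg$n_exc
  psz <- base_cfg$pattern_size
  e2i <- base_cfg$e_to_i_scale
  sizes <- spec$sizes
  gammas <- spec$gamma_ltd
  gs <- spec$g_max_ampa
  inhs <- spec$relative_inhibition
  thr0 <- .threshold_at(table, 0)

  dims <- c(length(inhs), length(gs), length(gammas), length(sizes))
  sep_sum <- comp_sum <- array(0, c(dims, n_profiles))
  for (p in seq_len(n_profiles)) {
    adjacency <- build_connectivity(base_cfg, seed = seed + 7919L * p)
    mask <- adjacency * 1L
    for (s in seq_len(n_sets)) {
      pats <- generate_pattern_set(max(sizes), base_cfg,
                                   seed = seed + 104729L * p + s)
      x_full <- pattern_matrix(pats, n)
      for (iz in seq_along(sizes)) {
        xs <- x_full[, seq_len(sizes[iz]), drop = FALSE]
        joint <- tcrossprod(xs)
        per <- rowSums(xs)
        n11 <- joint * mask
        ssum <- (matrix(per, n, n) + matrix(per, n, n, byrow = TRUE) -
                   2 * joint) * mask
        member <- xs > 0
        for (ig in seq_along(gammas)) {
          m <- n11 / (n11 + gammas[ig] * ssum)
          m[n11 == 0] <- 0
          d <- crossprod(m, xs) # unit-g_max drive [neuron, pattern]
          for (jg in seq_along(gs)) {
            g <- gs[jg]
            i_sep <- (psz * e2i * g) >= thr0
            i_comp <- ((psz - 1) * e2i * g) >= thr0
            for (ji in seq_along(inhs)) {
              g_gaba <- g * psz * conn * inhs[ji]
              thr_sep <- .threshold_at(table, if (i_sep) g_gaba else 0) / g
              thr_comp <- .threshold_at(table, if (i_comp) g_gaba else 0) / g
              sep_fail <- colSums((d >= thr_sep) & !member) > 0
              comp_fail <- colSums(member & (d < thr_comp)) / psz
              sep_sum[ji, jg, ig, iz, p] <-
                sep_sum[ji, jg, ig, iz, p] + mean(sep_fail)
              comp_sum[ji, jg, ig, iz, p] <-
                comp_sum[ji, jg, ig, iz, p] + mean(comp_fail)
            }
          }
        }
      }
    }
  }
  sep_prof <- sep_sum / n_sets # per-profile means
  comp_prof <- comp_sum / n_sets
  grid <- expand.grid(relative_inhibition = inhs, g_max_ampa = gs,
                      gamma_ltd = gammas, n_patterns = sizes,
                      KEEP.OUT.ATTRS = FALSE)
  sep_m <- apply(sep_prof, 1:4, mean)
  comp_m <- apply(comp_prof, 1:4, mean)
  semf <- if (n_profiles > 1) {
    function(a) apply(a, 1:4, stats::sd) / sqrt(n_profiles)
  } else function(a) array(0, dims)
  data.frame(connectivity = conn, g_max_ampa = grid$g_max_ampa,
             gamma_ltd = grid$gamma_ltd,
             relative_inhibition = grid$relative_inhibition,
             n_patterns = grid$n_patterns,
             sep_err = as.vector(sep_m), comp_err = as.vector(comp_m),
             max_err = pmax(as.vector(sep_m), as.vector(comp_m)),
             sep_sem = as.vector(semf(sep_prof)),
             comp_sem = as.vector(semf(comp_prof)))
}

#' Select the optimal balanced networks
#'
#' Within the database slice at the stated connectivity constraint and
#' memory load, returns the `top_k` parameter combinations with the
#' smallest `max_err` (the greater of the separation and completion error
#' rates). Ties are broken by smaller `|sep_err - comp_err|` (the more
#' evenly balanced network), then by lexicographic parameter order
#' (g_max_ampa, gamma_ltd, relative_inhibition) for reproducibility.
#'
#' @param db A [run_sweep()] database.
#' @param connectivity Connectivity constraint (default 0.5, the wild-type
#'   anatomical estimate).
#' @param n_patterns Memory load at which performance is judged
#'   (default 30).
#' @param top_k Number of networks to return (default 100).
#' @return The selected database rows, best first.
#' @export
select_optimal <- function(db, connectivity = 0.5, n_patterns = 30,
                           top_k = 100) {
  slice <- db[abs(db$connectivity - connectivity) < 1e-9 &
                db$n_patterns == n_patterns, ]
  if (nrow(slice) < top_k) {
    stop("database slice has ", nrow(slice), " records; top_k = ", top_k,
         " requested")
  }
  ord <- order(slice$max_err, abs(slice$sep_err - slice$comp_err),
               slice$g_max_ampa, slice$gamma_ltd, slice$relative_inhibition)
  out <- slice[ord[seq_len(top_k)], ]
  rownames(out) <- NULL
  out
}

# network_config from a database/optimal-set row.
config_from_row <- function(row, base = network_config()) {
  network_config(n_exc = base$n_exc, pattern_size = base$pattern_size,
                 connectivity_level = row$connectivity,
                 g_max_ampa = row$g_max_ampa, gamma_ltd = row$gamma_ltd,
                 relative_inhibition = row$relative_inhibition,
                 e_to_i_scale = base$e_to_i_scale)
}
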