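# Experiment drivers: benchmark campaigns feeding the rank tests,
# parameter-sensitivity sweeps, and the chain-rebuild pipeline.

algo_spec <- function(algorithm, cfg_fa, cfg_ada) {
  a <- toupper(sub("^AdaFa-", "", algorithm, ignore.case = TRUE))
  if (a == "FA") return(list(label = "FA", adaptive = FALSE, cfg = cfg_fa))
  if (a %in% paste0("S", 0:5)) {
    cfg <- cfg_ada
    cfg$strategy <- a
    return(list(label = paste0("AdaFa-", a), adaptive = TRUE, cfg = cfg))
  }
  stop("unknown algorithm: ", algorithm)
}

#' Run a benchmark campaign
#'
#' Runs each requested algorithm on each benchmark function for `trials`
#' independent runs (seed policy: `base_seed + trial - 1`), and summarizes
#' mean, standard deviation and success rate per (algorithm, function).
#' The summary matrix of means feeds the rank tests directly.
#'
#' @param algorithms character vector among `"FA"`, `"S1"` ... `"S5"`
#'   (or `"AdaFa-S1"` etc.).
#' @param functions benchmark names `"f1"` ... `"f12"`.
#' @param trials independent trials per cell.
#' @param dim problem dimension.
#' @param base_seed first seed; trial `k` uses `base_seed + k - 1`.
#' @param cfg_fa [fa_config()] used for `"FA"`.
#' @param cfg_ada [adafa_config()] template for the AdaFa variants (its
#'   `strategy` field is overridden per algorithm).
#' @param out_csv optional path: writes the summary as CSV.
#' @return A list with `summary` (data frame), `means` (a
#'   [results_matrix()] of algorithms x functions) and `records`
#'   (per-trial best values).
#' @export
run_campaign <- function(algorithms = c("FA", paste0("S", 1:5)),
                         functions = paste0("f", 1:12), trials = 30,
                         dim = 30, base_seed = 1,
                         cfg_fa = fa_config(), cfg_ada = adafa_config(),
                         out_csv = NULL) {
  stopifnot(trials >= 1)
  specs <- lapply(algorithms, algo_spec, cfg_fa = cfg_fa, cfg_ada = cfg_ada)
  records <- list()
  for (sp in specs) {
    for (fn in functions) {
      prob <- benchmark_problem(fn, dim = dim)
      vals <- vapply(seq_len(trials), function(k) {
        runner <- if (sp$adaptive) run_adafa else run_fa
        runner(prob, sp$cfg, seed = base_seed + k - 1, trace = FALSE)$best_value
      }, numeric(1))
      records[[length(records) + 1]] <- data.frame(
        algorithm = sp$label, fn = fn, trial = seq_len(trials),
        seed = base_seed + seq_len(trials) - 1, best_value = vals)
    }
  }
  rec <- do.call(rbind, records)
  summ <- do.call(rbind, lapply(split(rec, list(rec$algorithm, rec$fn),
                                      drop = TRUE), function(d) {
    prob <- benchmark_problem(d$fn[1], dim = dim)
    data.frame(algorithm = d$algorithm[1], fn = d$fn[1],
               mean = mean(d$best_value),
               sd = if (nrow(d) > 1) sd(d$best_value) else 0,
               success = success_rate(d$best_value, prob$success_threshold,
                                      optimum = if (prob$fun_id == 8)
                                        prob$optimum_value else NULL))
  }))
  rownames(summ) <- NULL
  labs <- vapply(specs, `[[`, character(1), "label")
  means <- matrix(NA_real_, length(labs), length(functions),
                  dimnames = list(labs, functions))
  for (r in seq_len(nrow(summ)))
    means[summ$algorithm[r], summ$fn[r]] <- summ$mean[r]
  optima <- vapply(functions, function(fn)
    benchmark_problem(fn, dim = dim)$optimum_value, numeric(1))
  means <- results_matrix(means, optima = optima)
  if (!is.null(out_csv)) write_results_matrix(means, out_csv)
  list(summary = summ, means = means, records = rec)
}

#' Parameter-sensitivity sweep
#'
#' Evaluates the adaptive optimizer over a grid of parameter pairs
#' (typically `delta` x `lambda`, or `g_min` x `g_max`), averaging the
#' final best value over `repeats` runs per cell on each requested
#' function.  Grid rows with `g_min >= g_max` are rejected.
#'
#' @param grid data frame whose columns name [adafa_config()] fields and
#'   whose rows are the parameter combinations to test.
#' @param functions benchmark names (the sensitivity set defaults to
#'   Sphere, Schwefel 2.22, Rosenbrock, Rastrigin, Ackley, Griewank).
#' @param repeats runs per cell.
#' @param dim problem dimension.
#' @param base_seed seed policy as in [run_campaign()].
#' @param cfg template [adafa_config()].
#' @return A data frame: the grid, one block per function, with the
#'   per-cell `mean_best`.
#' @export
sensitivity_sweep <- function(grid,
                              functions = c("f1", "f2", "f5", "f9", "f10",
                                            "f11"),
                              repeats = 20, dim = 30, base_seed = 1,
                              cfg = adafa_config()) {
  grid <- as.data.frame(grid)
  if (all(c("g_min", "g_max") %in% names(grid)) &&
      any(grid$g_min >= grid$g_max))
    stop("sweep grid contains g_min >= g_max")
  out <- list()
  for (fn in functions) {
    prob <- benchmark_problem(fn, dim = dim)
    mb <- vapply(seq_len(nrow(grid)), function(g) {
      cfg_g <- cfg
      cfg_g[names(grid)] <- as.list(grid[g, , drop = FALSE])
      mean(vapply(seq_len(repeats), function(k)
        run_adafa(prob, cfg_g, seed = base_seed + k - 1,
                  trace = FALSE)$best_value, numeric(1)))
    }, numeric(1))
    out[[fn]] <- cbind(data.frame(fn = fn), grid, mean_best = mb)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rebuild pipeline: geometry extraction, optional noise, rebuild, scoring
#'
#' For each input chain: extract the virtual bond geometry, optionally
#' perturb it with proportional Gaussian noise, rebuild the chain with the
#' per-atom adaptive firefly placement, and score the rebuilt trace
#' against the source (RMSD, TM-score, GDT-TS, GDT-HA).
#'
#' @param input a [ca_trace()], a list of traces, or a path to a PDB file
#'   (all chains with at least 5 C-alpha atoms are processed).
#' @param noise relative constraint noise fraction (e.g. `0.1`); 0 for
#'   noise-free constraints.
#' @param cfg per-atom optimizer config, as in [rebuild_chain()].
#' @param seed base seed; chain `k` uses `seed + k - 1`.
#' @param out_pdb optional path prefix: each rebuilt chain is written as
#'   `<prefix>_<chain>.pdb`.
#' @param out_csv optional path for the report CSV.
#' @return A data frame with one row per chain: residue count, noise
#'   level, the four scores, the worst per-atom energy and the number of
#'   flagged placements.
#' @export
rebuild_pipeline <- function(input, noise = 0,
                             cfg = adafa_config(pop_size = 24, max_gen = 150),
                             seed = 1, out_pdb = NULL, out_csv = NULL) {
  traces <- if (inherits(input, "ca_trace")) list(chain1 = input)
            else if (is.character(input)) read_all_chains(input)
            else input
  if (is.null(names(traces)))
    names(traces) <- paste0("chain", seq_along(traces))
  rows <- list()
  for (k in seq_along(traces)) {
    tr <- traces[[k]]
    geom <- extract_geometry(tr)
    set.seed(seed + k - 1)
    if (noise > 0) geom <- add_constraint_noise(geom, noise)
    rb <- rebuild_chain(geom, cfg = cfg)
    sc <- score_set(rb$trace, tr)
    if (!is.null(out_pdb))
      write_ca_pdb(rb$trace, paste0(out_pdb, "_", names(traces)[k], ".pdb"))
    rows[[k]] <- data.frame(
      chain = names(traces)[k], n_res = nrow(tr$coords), noise = noise,
      rmsd = sc$rmsd, tm = sc$tm, gdt_ts = sc$gdt_ts, gdt_ha = sc$gdt_ha,
      max_energy = max(rb$energies), n_flagged = length(rb$flagged))
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  if (!is.null(out_csv)) write.csv(rep, out_csv, row.names = FALSE)
  rep
}

read_all_chains <- function(path) {
  pdb <- bio3d::read.pdb(path)
  chains <- unique(pdb$atom$chain[pdb$atom$elety == "CA"])
  out <- list()
  for (ch in chains) {
    tr <- try(read_ca_trace(path, chain = ch), silent = TRUE)
    if (!inherits(tr, "try-error")) out[[ch]] <- tr
  }
  if (length(out) == 0) stop("no usable chains (>= 5 C-alpha) in ", path)
  out
}
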