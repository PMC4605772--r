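# Genetic-algorithm generator of klinotaxis-competent circuit ensembles.
# Real-valued genotype in [-1, 1], decoded linearly to the documented
# parameter ranges; the dorsal/ventral symmetry constraint is built into the
# genotype encoding (dorsal and ventral motor-neuron parameters share genes).

.genome_names <- c(
  "w_ON_AIYL", "w_ON_AIYR", "w_OFF_AIYL", "w_OFF_AIYR",
  "w_AIYL_AIZL", "w_AIYR_AIZR", "w_AIZL_SMB", "w_AIZR_SMB",
  "w_SMBL_self", "w_SMBR_self", "g_AIY", "g_AIZ",
  "theta_AIYL", "theta_AIYR", "theta_AIZL", "theta_AIZR",
  "theta_SMBL", "theta_SMBR", "w_PG", "w_NMJ", "tau", "N", "M"
)

#' Configuration of the evolutionary search
#'
#' Collects the genetic-algorithm settings and the per-parameter decoding
#' ranges.  Defaults define the standard study conditions of the package's
#' synthetic ensemble: tournament selection with elitism, Gaussian mutation
#' on a real-valued genotype, fitness equal to the chemotaxis index of
#' closed-loop runs from fixed random start poses, and a success threshold
#' of 0.75.
#'
#' @param pop_size population size.
#' @param generations number of generations (0 evaluates the random initial
#'   population only).
#' @param mutation_sd standard deviation of the Gaussian mutation, on the
#'   [-1, 1] genotype scale.
#' @param mutation_prob per-gene probability of mutating (sparse, large
#'   mutations explore the parameter space better here than dense small
#'   ones).
#' @param crossover_rate probability that an offspring is produced by
#'   uniform crossover of two tournament winners rather than by copying one.
#' @param tournament_size tournament size for selection.
#' @param elitism number of top individuals copied unchanged.
#' @param fitness_threshold chemotaxis index above which an individual
#'   counts as a successful klinotaxis circuit.
#' @param weight_range,bias_range,g_range,nmj_range,tau_range,nm_range
#'   decoding ranges for chemical-synapse/pattern-generator weights, biases,
#'   gap-junction conductances, the neuromuscular weight, the membrane time
#'   constant (s), and the integer sensory windows N and M (steps).
#' @param sensory_weight_range decoding range for the ON/OFF chemosensor
#'   weights.  The sensor potentials are perceived concentration changes
#'   (at most about 0.01 in magnitude), two orders of magnitude below the
#'   (0, 1) synaptic outputs driving every other connection, so the
#'   sensory weights scale correspondingly for the chemosensors to drive
#'   the interneurons across their sensitive range.
#' @param eval_duration closed-loop evaluation run length (s).
#' @param n_eval_starts number of start poses per evaluation (fitness is the
#'   mean chemotaxis index); poses are drawn once per run from the run seed.
#' @param start_distance start distance from the gradient peak (cm).
#' @param dt integration step (s).
#' @param arena_radius truncation radius (cm).
#' @return an object of class \code{evolution_config}.
#' @export
evolution_config <- function(pop_size = 60, generations = 200,
                             mutation_sd = 0.5, mutation_prob = 0.3,
                             crossover_rate = 0,
                             tournament_size = 3, elitism = 2,
                             fitness_threshold = 0.75,
                             weight_range = c(-15, 15),
                             sensory_weight_range = c(-1500, 1500),
                             bias_range = c(-15, 15),
                             g_range = c(0.01, 2.5),
                             nmj_range = c(-2, 2),
                             tau_range = c(0.1, 2),
                             nm_range = c(1, 210),
                             eval_duration = 300, n_eval_starts = 3,
                             start_distance = 2, dt = 0.01,
                             arena_radius = 10) {
  stopifnot(pop_size >= 2, generations >= 0, g_range[1] > 0,
            tau_range[1] > 0, nm_range[1] >= 1)
  structure(as.list(environment()), class = "evolution_config")
}

lin_map <- function(g, range) (g + 1) / 2 * (range[2] - range[1]) + range[1]

# Decode a [-1, 1] genotype into a dorsal/ventral-symmetric circuit.
decode_genome <- function(genome, cfg) {
  g <- stats::setNames(as.numeric(genome), .genome_names)
  wr <- cfg$weight_range
  nm <- function(x) round(lin_map(x, cfg$nm_range))
  swr <- cfg$sensory_weight_range
  circuit_params(
    w_ON_AIYL = lin_map(g[["w_ON_AIYL"]], swr),
    w_ON_AIYR = lin_map(g[["w_ON_AIYR"]], swr),
    w_OFF_AIYL = lin_map(g[["w_OFF_AIYL"]], swr),
    w_OFF_AIYR = lin_map(g[["w_OFF_AIYR"]], swr),
    w_AIYL_AIZL = lin_map(g[["w_AIYL_AIZL"]], wr),
    w_AIYR_AIZR = lin_map(g[["w_AIYR_AIZR"]], wr),
    w_AIZL_SMBDL = lin_map(g[["w_AIZL_SMB"]], wr),
    w_AIZL_SMBVL = lin_map(g[["w_AIZL_SMB"]], wr),
    w_AIZR_SMBDR = lin_map(g[["w_AIZR_SMB"]], wr),
    w_AIZR_SMBVR = lin_map(g[["w_AIZR_SMB"]], wr),
    w_SMBDL_SMBDL = lin_map(g[["w_SMBL_self"]], wr),
    w_SMBVL_SMBVL = lin_map(g[["w_SMBL_self"]], wr),
    w_SMBDR_SMBDR = lin_map(g[["w_SMBR_self"]], wr),
    w_SMBVR_SMBVR = lin_map(g[["w_SMBR_self"]], wr),
    g_AIY = lin_map(g[["g_AIY"]], cfg$g_range),
    g_AIZ = lin_map(g[["g_AIZ"]], cfg$g_range),
    theta_AIYL = lin_map(g[["theta_AIYL"]], cfg$bias_range),
    theta_AIYR = lin_map(g[["theta_AIYR"]], cfg$bias_range),
    theta_AIZL = lin_map(g[["theta_AIZL"]], cfg$bias_range),
    theta_AIZR = lin_map(g[["theta_AIZR"]], cfg$bias_range),
    theta_SMBDL = lin_map(g[["theta_SMBL"]], cfg$bias_range),
    theta_SMBVL = lin_map(g[["theta_SMBL"]], cfg$bias_range),
    theta_SMBDR = lin_map(g[["theta_SMBR"]], cfg$bias_range),
    theta_SMBVR = lin_map(g[["theta_SMBR"]], cfg$bias_range),
    w_PG = lin_map(g[["w_PG"]], wr),
    w_NMJ = lin_map(g[["w_NMJ"]], cfg$nmj_range),
    tau = lin_map(g[["tau"]], cfg$tau_range),
    N = nm(g[["N"]]), M = nm(g[["M"]])
  )
}

# Evaluate a whole population in one engine call per start pose.
evaluate_population <- function(pop, cfg, field, starts) {
  P <- t(vapply(seq_len(nrow(pop)),
                function(i) pack_params(decode_genome(pop[i, ], cfg)),
                numeric(31)))
  n_steps <- round(cfg$eval_duration / cfg$dt)
  ci <- matrix(0, nrow(pop), length(starts$x))
  for (j in seq_along(starts$x)) {
    res <- cpp_closed_loop(P, field_code(field), field$peak[1],
                           field$peak[2], field$c_peak, field$length_scale,
                           rep(starts$x[j], nrow(pop)),
                           rep(starts$y[j], nrow(pop)),
                           rep(starts$mu[j], nrow(pop)),
                           n_steps, cfg$dt, cfg$arena_radius,
                           FALSE, FALSE)
    ci[, j] <- pmax(0, pmin(1, 1 - res$mean_dist / res$init_dist))
  }
  rowMeans(ci)
}

ga_run <- function(cfg, field, seed) {
  set.seed(seed)
  n_genes <- length(.genome_names)
  ang <- stats::runif(cfg$n_eval_starts, 0, 2 * pi)
  starts <- list(x = field$peak[1] + cfg$start_distance * cos(ang),
                 y = field$peak[2] + cfg$start_distance * sin(ang),
                 mu = stats::runif(cfg$n_eval_starts, 0, 2 * pi))
  pop <- matrix(stats::runif(cfg$pop_size * n_genes, -1, 1),
                cfg$pop_size, n_genes)
  fit <- evaluate_population(pop, cfg, field, starts)
  history <- max(fit)
  gen <- 0
  while (gen < cfg$generations) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- matrix(0, cfg$pop_size, n_genes)
    n_elite <- min(cfg$elitism, cfg$pop_size)
    newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
    tournament <- function() {
      cand <- sample.int(cfg$pop_size, cfg$tournament_size)
      cand[which.max(fit[cand])]
    }
    for (i in (n_elite + 1):cfg$pop_size) {
      p1 <- pop[tournament(), ]
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        p2 <- pop[tournament(), ]
        mask <- stats::runif(n_genes) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mm <- stats::runif(n_genes) < cfg$mutation_prob
      child[mm] <- child[mm] + stats::rnorm(sum(mm), 0, cfg$mutation_sd)
      newpop[i, ] <- pmax(-1, pmin(1, child))
    }
    pop <- newpop
    new_fit <- evaluate_population(pop, cfg, field, starts)
    # elites are unchanged and start poses are fixed, so their fitness is too
    new_fit[seq_len(n_elite)] <- fit[ord[seq_len(n_elite)]]
    fit <- new_fit
    gen <- gen + 1
    history <- c(history, max(fit))
  }
  list(pop = pop, fitness = fit, history = history, starts = starts)
}

#' Evolve an ensemble of klinotaxis-competent circuits
#'
#' Runs independent seeded genetic-algorithm searches and collects every
#' individual whose chemotaxis index exceeds the success threshold.  Because
#' a converged population contains many near-identical genotypes,
#' \code{max_per_run} optionally thins each run's survivors to its top
#' fitness-ranked individuals whose genotypes differ by at least
#' \code{min_genotype_dist} (maximum absolute gene difference) from those
#' already kept.
#'
#' @param cfg an \code{evolution_config}.
#' @param field the \code{gradient_field} the circuits are evolved in.
#' @param n_runs number of independent searches.
#' @param seed base seed; run \code{i} uses \code{seed + i - 1}.
#' @param max_per_run cap on circuits kept per run (default unlimited).
#' @param min_genotype_dist genotype-distance floor used when thinning.
#' @return an object of class \code{circuit_ensemble}: a list of entries,
#'   each with elements \code{params}, \code{fitness}, \code{run},
#'   \code{seed}; attribute \code{history} holds per-run best-fitness
#'   traces.
#' @export
evolve_ensemble <- function(cfg, field = gradient_field(), n_runs = 1,
                            seed = 1, max_per_run = Inf,
                            min_genotype_dist = 0.1) {
  stopifnot(inherits(cfg, "evolution_config"))
  entries <- list()
  history <- list()
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1
    res <- ga_run(cfg, field, run_seed)
    ok <- which(res$fitness >= cfg$fitness_threshold)
    ok <- ok[order(res$fitness[ok], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ok) {
      if (length(kept) >= max_per_run) break
      if (length(kept) == 0 ||
          all(vapply(kept, function(k)
            max(abs(res$pop[i, ] - res$pop[k, ])), 0) >= min_genotype_dist))
        kept <- c(kept, i)
    }
    for (i in kept)
      entries[[length(entries) + 1]] <- list(
        params = decode_genome(res$pop[i, ], cfg),
        fitness = res$fitness[i], run = r, seed = run_seed)
    history[[r]] <- res$history
  }
  if (length(entries) == 0)
    warning("no individual reached the fitness threshold")
  structure(entries, class = "circuit_ensemble", history = history,
            config = cfg)
}

#' @export
print.circuit_ensemble <- function(x, ...) {
  cat(sprintf("Circuit ensemble: %d successful circuits from %d run(s)\n",
              length(x), length(attr(x, "history"))))
  if (length(x))
    cat(sprintf("  fitness range [%.3f, %.3f]\n",
                min(vapply(x, `[[`, 0, "fitness")),
                max(vapply(x, `[[`, 0, "fitness"))))
  invisible(x)
}

#' Manifest table of an ensemble
#' @param x a \code{circuit_ensemble}.
#' @param ... unused.
#' @return data frame with circuit id, run, seed, fitness.
#' @export
as.data.frame.circuit_ensemble <- function(x, ...) {
  data.frame(id = seq_along(x),
             run = vapply(x, `[[`, 0, "run"),
             seed = vapply(x, `[[`, 0, "seed"),
             fitness = vapply(x, `[[`, 0, "fitness"))
}

#' Write an ensemble as one parameter file per circuit plus a manifest
#' @param ens a \code{circuit_ensemble}.
#' @param dir destination directory.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ens))
    write_circuit_params(ens[[i]]$params,
                         file.path(dir, sprintf("circuit_%03d.txt", i)))
  utils::write.table(as.data.frame(ens), file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a packaged fixture circuit
#'
#' The package ships frozen, klinotaxis-competent parameter sets produced by
#' its own evolutionary search (synthetic circuits; the files are committed
#' so downstream analyses are deterministic).  The \code{"best"} fixture is
#' the highest-scoring circuit that also exhibits the ensemble-typical
#' information architecture (left/right information asymmetry in AIY,
#' symmetry in AIZ).
#'
#' @param name fixture name.
#' @return a \code{circuit_params} object.
#' @export
load_fixture <- function(name = "best") {
  dir <- system.file("extdata", package = "klinfo")
  avail <- sub("^circuit_(.*)_synthetic\\.txt$", "\\1",
               list.files(dir, pattern = "^circuit_.*_synthetic\\.txt$"))
  if (!name %in% avail)
    stop("unknown fixture \"", name, "\"; available: ",
         paste(avail, collapse = ", "))
  read_circuit_params(file.path(dir,
                                sprintf("circuit_%s_synthetic.txt", name)))
}
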