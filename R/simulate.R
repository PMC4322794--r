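#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with validated
#' defaults. The defaults describe the study conditions the pipeline is
#' validated under: a two-condition expression contrast over 2,000 genes
#' with log2 fold-change noise of sd 0.5 and one planted 20-gene metabolite
#' set shifted by +1 log2 unit; a toy compartment-less network of 30
#' metabolites and 60 reactions; uniformly labeled MID truths convolved with
#' natural abundance; exponential growth at k = ln(8)/72 per hour over 72 h
#' with glucose consumed and lactate excreted; and a four-phase
#' mitochondrial stress test whose FCCP phase sits 59% above basal.
#'
#' Each generator consumes its own RNG stream derived from `seed` by a fixed
#' offset, so adding one generator call to a script does not perturb the
#' output of the others.
#'
#' @param seed master seed
#' @param n_genes size of the gene pool (and expression universe)
#' @param n_metabolites,n_reactions random network dimensions (dedicated
#'   reactions for planted metabolites are added on top)
#' @param genes_per_reaction integer range, genes drawn per reaction
#' @param metabolites_per_reaction integer range, participants per reaction
#' @param n_pathways number of pathway labels assigned to reactions
#' @param planted tibble with columns `metabolite_id`, `effect` (log2
#'   units, sign = direction) and `n_genes_set` (exact size of the planted
#'   metabolite's gene set)
#' @param noise_sd sd of the per-gene log2 fold-change noise
#' @param n_replicates samples per condition
#' @param fpkm_meanlog,fpkm_sdlog log-normal baseline FPKM parameters
#' @param fpkm_threshold expression floor that planted genes are guaranteed
#'   to clear in both conditions
#' @param mid_truth tibble with columns `metabolite_id`, `formula`,
#'   `n_tracer`, `truth` (list-column of true MID vectors)
#' @param mid_noise_sd multiplicative measurement noise on convolved MIDs
#' @param growth list: `X0` (cells at t = 0), `k` (per hour), `t_hours`
#'   (sampling grid starting at 0), and a tibble `metabolites` with
#'   `metabolite_id`, `alpha_true` (nmol/1e6 cells/h, excretion positive)
#'   and `m0_nmol`
#' @param ocr list: `means` (named basal/oligomycin/fccp/rotenone), `sd`,
#'   `n_per_phase`
#' @return a `sim_config` list
#' @export
sim_config <- function(
    seed = 1,
    n_genes = 2000,
    n_metabolites = 30,
    n_reactions = 60,
    genes_per_reaction = c(2, 8),
    metabolites_per_reaction = c(2, 3),
    n_pathways = 6,
    planted = tibble(metabolite_id = "M_planted", effect = 1.0,
                     n_genes_set = 20),
    noise_sd = 0.5,
    n_replicates = 1,
    fpkm_meanlog = log(50),
    fpkm_sdlog = 1,
    fpkm_threshold = 5,
    mid_truth = tibble(
      metabolite_id = c("lactate", "succinate", "glutamate"),
      formula = c("C3H5O3", "C4H4O4", "C5H8NO4"),
      n_tracer = c(3L, 4L, 5L),
      truth = list(c(0.3, 0, 0, 0.7), c(0.5, 0.1, 0.3, 0.05, 0.05),
                   c(0.4, 0, 0.15, 0.05, 0.05, 0.35))),
    mid_noise_sd = 0,
    growth = list(
      X0 = 1e5, k = log(8) / 72, t_hours = c(0, 24, 48, 72),
      metabolites = tibble(
        metabolite_id = c("glucose", "lactate"),
        alpha_true = c(-300, 500),
        m0_nmol = c(50000, 0))),
    ocr = list(means = c(basal = 100, oligomycin = 40, fccp = 159,
                         rotenone = 10),
               sd = 3, n_per_phase = 3)) {
  assert_scalar_number(seed, "seed")
  assert_count(n_genes, "n_genes")
  assert_count(n_metabolites, "n_metabolites")
  assert_count(n_reactions, "n_reactions")
  assert_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  assert_count(n_replicates, "n_replicates")
  stopifnot(length(genes_per_reaction) == 2,
            genes_per_reaction[1] <= genes_per_reaction[2],
            genes_per_reaction[1] >= 0,
            length(metabolites_per_reaction) == 2)
  if (genes_per_reaction[2] > n_genes) {
    abort("`genes_per_reaction` exceeds the gene pool size.")
  }
  planted <- as_tibble(planted)
  if (nrow(planted)) {
    stopifnot(all(c("metabolite_id", "effect", "n_genes_set") %in%
                    names(planted)))
    if (any(!is.finite(planted$effect))) abort("planted effects must be finite.")
    if (any(planted$n_genes_set < 1 | planted$n_genes_set > n_genes)) {
      abort("`n_genes_set` must be in [1, n_genes].")
    }
  }
  structure(
    list(seed = seed, n_genes = n_genes, n_metabolites = n_metabolites,
         n_reactions = n_reactions, genes_per_reaction = genes_per_reaction,
         metabolites_per_reaction = metabolites_per_reaction,
         n_pathways = n_pathways, planted = planted, noise_sd = noise_sd,
         n_replicates = n_replicates, fpkm_meanlog = fpkm_meanlog,
         fpkm_sdlog = fpkm_sdlog, fpkm_threshold = fpkm_threshold,
         mid_truth = as_tibble(mid_truth), mid_noise_sd = mid_noise_sd,
         growth = growth, ocr = ocr),
    class = "sim_config")
}

gene_pool <- function(config) sprintf("g%04d", seq_len(config$n_genes))

#' Simulate a toy metabolic network
#'
#' Random bipartite reaction-metabolite structure: each reaction draws its
#' participants from the metabolite pool and its genes without replacement
#' from the gene pool, and is assigned one of `n_pathways` pathway labels.
#' Planted metabolites are kept out of the random pool and instead receive
#' dedicated reactions whose gene lists partition exactly `n_genes_set`
#' genes, so the metabolite gene set later built for them has a known size.
#'
#' @param config a [sim_config()]
#' @return a [metabolic_network()]
#' @export
sim_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_offset(config$seed, 101, {
    genes <- gene_pool(config)
    planted_ids <- config$planted$metabolite_id
    mets <- union(sprintf("M%03d", seq_len(config$n_metabolites)),
                  planted_ids)
    pool <- setdiff(mets, planted_ids)
    if (length(pool) < max(config$metabolites_per_reaction)) {
      abort("too few non-planted metabolites for the reaction size range.")
    }
    pathways <- sprintf("PW%02d", seq_len(config$n_pathways))

    rxns <- purrr::map(seq_len(config$n_reactions), function(i) {
      nm <- sample(config$metabolites_per_reaction[1]:
                     config$metabolites_per_reaction[2], 1)
      ng <- sample(config$genes_per_reaction[1]:
                     config$genes_per_reaction[2], 1)
      tibble(reaction_id = sprintf("R%04d", i),
             pathway = sample(pathways, 1),
             metabolites = list(sample(pool, nm)),
             genes = list(if (ng > 0) sample(genes, ng) else character()))
    }) |> purrr::list_rbind()

    # dedicated reactions give each planted metabolite an exact-size set
    extra <- list()
    rid <- config$n_reactions
    for (i in seq_len(nrow(config$planted))) {
      row <- config$planted[i, ]
      set_genes <- sample(genes, row$n_genes_set)
      chunk <- max(1, config$genes_per_reaction[2])
      starts <- seq(1, length(set_genes), by = chunk)
      for (sft in starts) {
        rid <- rid + 1
        extra[[length(extra) + 1]] <- tibble(
          reaction_id = sprintf("R%04d", rid),
          pathway = sample(pathways, 1),
          metabolites = list(row$metabolite_id),
          genes = list(set_genes[sft:min(sft + chunk - 1,
                                         length(set_genes))]))
      }
    }
    rxns <- bind_rows(rxns, purrr::list_rbind(extra))
    metabolic_network(
      tibble(metabolite_id = mets, name = mets, compartment_id = "c"),
      rxns)
  })
}

#' Simulate a two-condition expression table with planted signal
#'
#' Baseline FPKM values are log-normal; condition-B values are
#' `baseline * 2^(delta + eps)` where `delta` is the planted log2 effect for
#' genes belonging to a planted metabolite's gene set (0 otherwise) and
#' `eps ~ Normal(0, noise_sd)`. Planted genes are floored at the expression
#' threshold in both conditions so the FPKM filter cannot silently remove
#' the signal.
#'
#' @param config a [sim_config()]
#' @param network the matching [sim_network()] output
#' @return list with `expr` (tibble `gene_id` + one column per sample) and
#'   `design` (tibble `sample`, `condition` with conditions `"A"`, `"B"`)
#' @export
sim_expression <- function(config, network) {
  stopifnot(inherits(config, "sim_config"),
            inherits(network, "metabolic_network"))
  with_seed_offset(config$seed, 202, {
    genes <- gene_pool(config)
    n <- length(genes)
    delta <- setNames(numeric(n), genes)
    if (nrow(config$planted)) {
      sets <- build_metabolite_gene_sets(network, min_size = 1,
                                         max_size = Inf)
      for (i in seq_len(nrow(config$planted))) {
        row <- config$planted[i, ]
        memb <- sets$genes[[match(row$metabolite_id, sets$set_id)]]
        delta[memb] <- delta[memb] + row$effect
      }
    }
    planted_genes <- names(delta)[delta != 0]
    n_rep <- config$n_replicates
    expr <- tibble(gene_id = genes)
    design <- tibble(sample = character(), condition = character())
    baseline <- rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
    baseline[genes %in% planted_genes] <-
      pmax(baseline[genes %in% planted_genes], config$fpkm_threshold)
    for (r in seq_len(n_rep)) {
      sa <- if (n_rep == 1) "A" else sprintf("A_%d", r)
      sb <- if (n_rep == 1) "B" else sprintf("B_%d", r)
      eps <- rnorm(n, 0, config$noise_sd)
      fpkm_b <- baseline * 2^(delta + eps)
      fpkm_b[genes %in% planted_genes] <-
        pmax(fpkm_b[genes %in% planted_genes], config$fpkm_threshold)
      expr[[sa]] <- baseline
      expr[[sb]] <- fpkm_b
      design <- bind_rows(design,
                          tibble(sample = c(sa, sb), condition = c("A", "B")))
    }
    list(expr = expr, design = design)
  })
}

#' Simulate measured mass-isotopomer distributions
#'
#' Convolves each true MID in `config$mid_truth` with natural isotope
#' abundance (the forward model of [correct_mid()]) and applies optional
#' multiplicative Gaussian noise per fraction.
#'
#' @param config a [sim_config()]
#' @return tibble in the layout [correct_mid_table()] accepts
#'   (`metabolite_id`, `formula`, `n_tracer`, `M0` ...)
#' @export
sim_mids <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_offset(config$seed, 303, {
    truth <- config$mid_truth
    nmax <- max(truth$n_tracer)
    rows <- purrr::map(seq_len(nrow(truth)), function(i) {
      row <- truth[i, ]
      tv <- row$truth[[1]]
      if (length(tv) != row$n_tracer + 1 || any(tv < 0) || sum(tv) <= 0) {
        abort(sprintf("invalid truth MID for '%s'.", row$metabolite_id))
      }
      measured <- convolve_mid(
        mid_vector(tv, elemental_formula(row$formula, row$n_tracer),
                   row$metabolite_id))$fractions
      if (config$mid_noise_sd > 0) {
        measured <- pmax(
          measured * (1 + rnorm(length(measured), 0, config$mid_noise_sd)),
          0)
      }
      vals <- rep(NA_real_, nmax + 1)
      vals[seq_along(measured)] <- measured
      bind_cols(row[c("metabolite_id", "formula", "n_tracer")],
                as_tibble(setNames(as.list(vals), paste0("M", 0:nmax))))
    })
    purrr::list_rbind(rows)
  })
}

#' Simulate spent-media growth courses
#'
#' Exact exponential growth `X(t) = X0 * exp(k t)`; metabolite amounts
#' follow the planted exchange rate exactly:
#' `M(t) = m0 + alpha * 1e-6 * X0 * (exp(k t) - 1) / k`.
#'
#' @param config a [sim_config()]
#' @return tibble: `metabolite_id`, `t_hours`, `cell_count`,
#'   `metabolite_nmol`
#' @export
sim_growth_course <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$growth
  t <- g$t_hours
  stopifnot(t[1] == 0, all(diff(t) > 0), g$X0 > 0)
  X <- g$X0 * exp(g$k * t)
  cell_hours <- if (abs(g$k) < 1e-12) g$X0 * t else
    g$X0 * (exp(g$k * t) - 1) / g$k
  purrr::map(seq_len(nrow(g$metabolites)), function(i) {
    row <- g$metabolites[i, ]
    tibble(metabolite_id = row$metabolite_id, t_hours = t, cell_count = X,
           metabolite_nmol = row$m0_nmol + row$alpha_true * 1e-6 * cell_hours)
  }) |> purrr::list_rbind()
}

#' Simulate an oxygen-consumption trace
#'
#' Draws `n_per_phase` measurements per stress-test phase around the
#' configured phase means with Gaussian noise, clamped at 0.
#'
#' @param config a [sim_config()]
#' @return tibble: `phase`, `ocr`
#' @export
sim_ocr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_offset(config$seed, 505, {
    o <- config$ocr
    stopifnot(all(c("basal", "oligomycin", "fccp", "rotenone") %in%
                    names(o$means)))
    purrr::map(names(o$means), function(ph) {
      tibble(phase = ph,
             ocr = pmax(rnorm(o$n_per_phase, o$means[[ph]], o$sd), 0))
    }) |> purrr::list_rbind()
  })
}

#' Simulate random annotation-style gene sets
#'
#' GO-term-like sets drawn uniformly from the gene pool, for exercising the
#' GMT route of the pipeline.
#'
#' @param config a [sim_config()]
#' @param n_sets number of sets
#' @param size_range set-size range
#' @return a [gene_set_collection()] with provenance `"go"`
#' @export
sim_go_sets <- function(config, n_sets = 15, size_range = c(10, 40)) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_offset(config$seed, 606, {
    genes <- gene_pool(config)
    sets <- purrr::map(seq_len(n_sets), function(i) {
      tibble(set_id = sprintf("GO:%07d", i),
             name = sprintf("simulated term %d", i),
             genes = list(sample(genes, sample(size_range[1]:size_range[2],
                                               1))))
    }) |> purrr::list_rbind()
    gene_set_collection(sets, "go")
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates every input the pipeline consumes — network TSV, expression
#' TSV + design TSV, GO-style GMT, measured MID CSV, growth-course CSV, OCR
#' CSV — plus a `truth.json` manifest recording the planted ground truth.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return named list of file paths, invisibly
#' @export
simulate_fixtures <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  network <- sim_network(config)
  ex <- sim_expression(config, network)

  paths <- list(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    go_gmt = file.path(dir, "go.gmt"),
    mids = file.path(dir, "mids.csv"),
    growth = file.path(dir, "growth.csv"),
    ocr = file.path(dir, "ocr.csv"),
    truth = file.path(dir, "truth.json"))

  write_network_tsv(network, paths$network)
  readr::write_tsv(ex$expr, paths$expression, progress = FALSE)
  readr::write_tsv(ex$design, paths$design, progress = FALSE)
  write_gmt(sim_go_sets(config), paths$go_gmt)
  readr::write_csv(sim_mids(config), paths$mids, progress = FALSE)
  readr::write_csv(sim_growth_course(config), paths$growth, progress = FALSE)
  readr::write_csv(sim_ocr(config), paths$ocr, progress = FALSE)

  truth <- list(
    seed = config$seed,
    planted = config$planted,
    mid_truth = tibble(metabolite_id = config$mid_truth$metabolite_id,
                       truth = vapply(config$mid_truth$truth, paste,
                                      character(1), collapse = ",")),
    alpha_true = config$growth$metabolites,
    ocr_means = as.list(config$ocr$means))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write a metabolic network in the tabular dialect
#'
#' Inverse of [read_network_tsv()]: one row per (reaction, participant)
#' with semicolon-joined gene lists.
#'
#' @param network a [metabolic_network()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_network_tsv <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  long <- tibble(
    reaction_id = rep(rx$reaction_id, lengths(rx$metabolites)),
    metabolite_id = unlist(rx$metabolites),
    role = "participant",
    genes = rep(vapply(rx$genes, paste, character(1), collapse = ";"),
                lengths(rx$metabolites)),
    pathway = rep(rx$pathway, lengths(rx$metabolites)))
  long <- left_join(long, network$metabolites, by = "metabolite_id") |>
    rename(metabolite_name = "name")
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
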