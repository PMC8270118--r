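#' Simulation configuration for a synthetic RNAi screen study
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults encode the study design the analysis modules assume: a
#' 12-species Drosophila tree with a 6-stage root-to-focal path, 11,354
#' phenotyped genes of which roughly 702 are genus-specific, a true
#' essential proportion of 0.35 on every branch, per-library
#' knockdown-efficiency Beta distributions matched to mean
#' percent-of-control 38.1 (GD-like) and 48.6 (KK-like) with
#' P(efficiency <= 30%) of 0.53 and 0.37, a hard lethality-detection
#' threshold at 30% of control, a false-positive rate of 1.6%, and a 24%
#' rate of confounding 40D3 insertions among KK lines.
#'
#' @param n_genes Number of genes to simulate.
#' @param tree Newick string/file or `phylo`; must contain `focal`.
#' @param focal Focal species leaf label.
#' @param branch_probs Probability that a gene originates on each branch
#'   `0..K` of the root-to-focal path; sums to 1.
#' @param p_essential_per_branch True essentiality probability per branch
#'   (length `K + 1` or scalar).
#' @param mechanism_probs Named probabilities for origination mechanisms
#'   `DNA-duplication`, `RNA-duplication`, `orphan`; sums to 1. Applied to
#'   genes on branches >= 1; branch-0 (old) genes are labeled `unknown`.
#' @param efficiency_params Named list of per-library Beta shape pairs
#'   (`shape1`, `shape2`) for the knockdown-efficiency distribution on
#'   (0, 1], scaled to percent.
#' @param detection_threshold Percent-of-control below-or-at which an
#'   essential gene's knockdown is detected as lethal (tau, in (0, 100]).
#' @param detection_model `"threshold"` (hard cutoff at tau, default) or
#'   `"sigmoid"` (logistic detection probability centred at tau with scale
#'   `sigmoid_scale`).
#' @param sigmoid_scale Scale (percent) of the sigmoid detection model.
#' @param fp_rate Probability a non-essential gene's line is called lethal
#'   (off-target false positive).
#' @param p_40d3 Probability a KK line carries the confounding 40D3
#'   insertion.
#' @param p_recombined Probability a 40D3-carrying line has been recombined
#'   back to 30B3-only (and is therefore usable).
#' @param library_probs Named probabilities that a gene's line comes from
#'   each library (`GD`, `KK`); sums to 1.
#' @param n_screen_replicates Number of replicate screens to emit.
#' @param replicate_mode `"same_line"`: replicate screens re-count progeny
#'   of the same lines (same efficiency, same underlying call);
#'   `"new_driver"`: each replicate redraws efficiency, emulating
#'   independent lines/drivers against the same genes.
#' @param ct_noise_sd Per-well qPCR Ct noise SD, in cycles.
#' @param n_qpcr_lines Number of usable lines per library given a qPCR
#'   efficiency assay.
#' @param paralog_fraction Fraction of young (branch >= 1) genes given a
#'   simulated paralog partner.
#' @param compensation_factor Fold-change of paralog expression in a
#'   knockout of its partner, applied when similarity >=
#'   `compensation_similarity` (>= 1).
#' @param compensation_similarity Sequence-similarity threshold above which
#'   compensation operates; default 0.9.
#' @param n_knockout_genes Number of paralog-bearing genes assayed in the
#'   synthetic knockout-expression experiment.
#' @param loss_rate Per-species probability that a gene present in the
#'   origin clade was secondarily lost (0 disables losses; losses never
#'   remove the focal species).
#' @param expression_cv Coefficient of variation of knockout-expression
#'   replicates.
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 11354,
    tree = default_drosophila_tree(),
    focal = "D_melanogaster",
    branch_probs = NULL,
    p_essential_per_branch = 0.35,
    mechanism_probs = c("DNA-duplication" = 0.60, "RNA-duplication" = 0.15,
                        orphan = 0.25),
    efficiency_params = list(GD = c(shape1 = 0.271771, shape2 = 0.441538),
                             KK = c(shape1 = 0.574271, shape2 = 0.607357)),
    detection_threshold = 30,
    detection_model = c("threshold", "sigmoid"),
    sigmoid_scale = 5,
    fp_rate = 0.016,
    p_40d3 = 0.24,
    p_recombined = 41 / 47,
    library_probs = c(GD = 0.5, KK = 0.5),
    n_screen_replicates = 2,
    replicate_mode = c("same_line", "new_driver"),
    ct_noise_sd = 0.2,
    n_qpcr_lines = 75,
    paralog_fraction = 0.5,
    compensation_factor = 2,
    compensation_similarity = 0.9,
    n_knockout_genes = 10,
    loss_rate = 0,
    expression_cv = 0.05,
    seed = 1) {
  detection_model <- match.arg(detection_model)
  replicate_mode <- match.arg(replicate_mode)
  stree <- species_tree(tree, focal)
  K <- stree$K
  if (is.null(branch_probs)) {
    # study-like mix: ~93.8% of phenotyped genes predate the genus,
    # the rest spread evenly over the six internal stages
    branch_probs <- c(10652, rep(702 / K, K)) / 11354
  }
  abort_if(length(branch_probs) != K + 1L,
           "branch_probs must have length K + 1 = %d", K + 1L)
  check_prob_vector(branch_probs, "branch_probs")
  check_prob_vector(mechanism_probs, "mechanism_probs")
  abort_if(!all(c("DNA-duplication", "RNA-duplication", "orphan") %in% names(mechanism_probs)),
           "mechanism_probs must be named DNA-duplication/RNA-duplication/orphan")
  if (length(p_essential_per_branch) == 1L) {
    p_essential_per_branch <- rep(p_essential_per_branch, K + 1L)
  }
  abort_if(length(p_essential_per_branch) != K + 1L,
           "p_essential_per_branch must be scalar or length K + 1 = %d", K + 1L)
  check_prob_vector(p_essential_per_branch, "p_essential_per_branch", sum_to_one = FALSE)
  check_prob_vector(c(fp_rate, p_40d3, p_recombined, loss_rate, paralog_fraction),
                    "rate parameters", sum_to_one = FALSE)
  check_prob_vector(library_probs, "library_probs")
  abort_if(!is_count(n_genes) || n_genes < 1, "n_genes must be a positive integer")
  abort_if(!(detection_threshold > 0 && detection_threshold <= 100),
           "detection_threshold must lie in (0, 100]")
  abort_if(ct_noise_sd < 0, "ct_noise_sd must be >= 0")
  abort_if(compensation_factor < 1, "compensation_factor must be >= 1")
  for (lib in names(efficiency_params)) {
    p <- efficiency_params[[lib]]
    abort_if(!all(c("shape1", "shape2") %in% names(p)) || any(p <= 0),
             "efficiency_params$%s must give positive shape1/shape2", lib)
  }
  structure(
    list(n_genes = as.integer(n_genes), tree = stree,
         branch_probs = branch_probs,
         p_essential_per_branch = p_essential_per_branch,
         mechanism_probs = mechanism_probs,
         efficiency_params = efficiency_params,
         detection_threshold = detection_threshold,
         detection_model = detection_model, sigmoid_scale = sigmoid_scale,
         fp_rate = fp_rate, p_40d3 = p_40d3, p_recombined = p_recombined,
         library_probs = library_probs,
         n_screen_replicates = as.integer(n_screen_replicates),
         replicate_mode = replicate_mode,
         ct_noise_sd = ct_noise_sd, n_qpcr_lines = as.integer(n_qpcr_lines),
         paralog_fraction = paralog_fraction,
         compensation_factor = compensation_factor,
         compensation_similarity = compensation_similarity,
         n_knockout_genes = as.integer(n_knockout_genes),
         loss_rate = loss_rate, expression_cv = expression_cv,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a complete synthetic screen dataset
#'
#' Generates, deterministically given the config seed, a species tree,
#' a gene-by-species presence matrix consistent with single-gain evolution
#' (plus optional stochastic losses), per-gene annotations, replicated
#' screen tables with progeny counts and phenotype calls, a qPCR Ct table
#' for a subset of lines, a knockout-expression table for paralog pairs,
#' and the full ground truth.
#'
#' Detection model: an essential gene's line is called lethal iff its
#' simulated knockdown efficiency (percent-of-control) is at or below the
#' detection threshold tau; non-essential genes are called lethal with
#' probability `fp_rate` (off-target false positives); KK lines carrying a
#' non-recombined 40D3 insertion are always lethal (landing-site artifact).
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_bundle`: `config`, `tree` (newick),
#'   `presence`, `annotations`, `screens` (list of data.frames), `qpcr`,
#'   `knockout`, `truth_genes`, `truth_lines`.
#' @export
simulate_dataset <- function(config) {
  abort_if(!inherits(config, "simulation_config"), "config must be a simulation_config")
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  tr <- cfg$tree
  K <- tr$K
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))

  branch <- sample(0:K, n, replace = TRUE, prob = cfg$branch_probs)
  essential <- stats::rbinom(n, 1, cfg$p_essential_per_branch[branch + 1L]) == 1
  mechanism <- rep("unknown", n)
  young <- branch >= 1L
  if (any(young)) {
    mechanism[young] <- sample(names(cfg$mechanism_probs), sum(young),
                               replace = TRUE, prob = cfg$mechanism_probs)
  }

  # presence matrix: species attached at or below the origin branch carry
  # the gene; optional secondary losses inside the clade (never the focal)
  species <- tr$phylo$tip.label
  present <- outer(branch, tr$attachment[species], `<=`)
  colnames(present) <- species
  if (cfg$loss_rate > 0) {
    lose <- matrix(stats::runif(length(present)) < cfg$loss_rate, nrow = n)
    lose[, species == tr$focal] <- FALSE
    present <- present & !lose
  }
  presence <- data.frame(gene_id = gene_id, 1 * present,
                         check.names = FALSE, stringsAsFactors = FALSE)

  # paralog pairs among young genes
  paralog_id <- rep(NA_character_, n)
  similarity <- rep(NA_real_, n)
  paired <- young & stats::runif(n) < cfg$paralog_fraction
  paralog_id[paired] <- paste0("p_", gene_id[paired])
  similarity[paired] <- stats::runif(sum(paired), 0.6, 1)

  annotations <- data.frame(gene_id = gene_id, mechanism = mechanism,
                            paralog_id = paralog_id, similarity = similarity,
                            stringsAsFactors = FALSE)

  # one line per gene; library membership, landing sites, efficiency
  library <- sample(names(cfg$library_probs), n, replace = TRUE,
                    prob = cfg$library_probs)
  is_kk <- library == "KK"
  has_30B3 <- is_kk
  has_40D3 <- is_kk & stats::runif(n) < cfg$p_40d3
  recombined <- has_40D3 & stats::runif(n) < cfg$p_recombined

  draw_efficiency <- function(lib) {
    out <- numeric(length(lib))
    for (lb in unique(lib)) {
      p <- cfg$efficiency_params[[lb]]
      abort_if(is.null(p), "no efficiency_params for library %s", lb)
      idx <- lib == lb
      out[idx] <- 100 * stats::rbeta(sum(idx), p[["shape1"]], p[["shape2"]])
    }
    pmax(out, 1e-6)
  }

  detect_lethal <- function(eff, ess) {
    detected <- if (cfg$detection_model == "threshold") {
      eff <= cfg$detection_threshold
    } else {
      stats::runif(length(eff)) <
        stats::plogis((cfg$detection_threshold - eff) / cfg$sigmoid_scale)
    }
    fp <- stats::runif(length(eff)) < cfg$fp_rate
    state <- ifelse(ess, detected, fp)
    off_target <- !ess & fp
    list(state = state, off_target = off_target)
  }

  efficiency <- draw_efficiency(library)
  det <- detect_lethal(efficiency, essential)
  artifact <- has_40D3 & !recombined

  make_screen <- function(rep_idx, eff, lethal_state, off_target) {
    state <- lethal_state | artifact
    gfp <- stats::rpois(n, 100) + 1L
    nongfp <- ifelse(state,
                     stats::rbinom(n, gfp, 0.02),
                     stats::rbinom(n, gfp, 0.90))
    data.frame(
      line_id = sprintf("L%05d_r%d", seq_len(n), rep_idx),
      gene_id = gene_id, library = library,
      has_30B3 = has_30B3, has_40D3 = has_40D3, recombined = recombined,
      driver = if (rep_idx == 1L || cfg$replicate_mode == "same_line")
        "Act5C-GAL4" else "aTub84B-GAL4",
      gfp_count = gfp, nongfp_count = nongfp,
      phenotype = ifelse(state, "lethal", "non-lethal"),
      stringsAsFactors = FALSE
    )
  }

  screens <- vector("list", cfg$n_screen_replicates)
  line_eff <- efficiency
  line_state <- det$state
  line_off <- det$off_target
  for (r in seq_len(cfg$n_screen_replicates)) {
    if (r > 1L && cfg$replicate_mode == "new_driver") {
      line_eff <- draw_efficiency(library)
      d <- detect_lethal(line_eff, essential)
      line_state <- d$state
      line_off <- d$off_target
    }
    screens[[r]] <- make_screen(r, line_eff, line_state, line_off)
  }
  names(screens) <- paste0("screen_", seq_along(screens))

  # qPCR assay of usable lines, per library, from true (replicate-1) efficiency
  usable <- !artifact
  qpcr <- NULL
  for (lb in names(cfg$library_probs)) {
    idx <- which(usable & library == lb)
    if (length(idx) == 0) next
    idx <- utils::head(idx, cfg$n_qpcr_lines)
    tabs <- lapply(idx, function(i) {
      w <- simulate_qpcr(efficiency[i], n_reps = 3, noise_sd = cfg$ct_noise_sd)
      w$sample_id <- paste0(screens[[1]]$line_id[i], "_", w$condition, "_", w$replicate)
      w$line_id <- screens[[1]]$line_id[i]
      w$gene_id <- gene_id[i]
      w$library <- lb
      w
    })
    qpcr <- rbind(qpcr, do.call(rbind, tabs))
  }
  if (!is.null(qpcr)) {
    qpcr <- qpcr[c("sample_id", "line_id", "gene_id", "library",
                   "gene_role", "condition", "replicate", "ct")]
  }

  # knockout-expression experiment on paralog-bearing young genes
  ko_idx <- utils::head(which(paired), cfg$n_knockout_genes)
  knockout <- NULL
  if (length(ko_idx) > 0) {
    reps <- 3L
    rows <- lapply(ko_idx, function(i) {
      comp <- similarity[i] >= cfg$compensation_similarity
      fold <- if (comp) cfg$compensation_factor else 1
      draw <- function(mu) pmax(mu * (1 + stats::rnorm(reps, 0, cfg$expression_cv)), 1e-6)
      make <- function(assay, role, mu_mut, mu_wt) {
        data.frame(
          mutant_gene = gene_id[i], assay_gene = assay, gene_role = role,
          condition = rep(c("mutant", "wt"), each = reps),
          replicate = rep(seq_len(reps), 2),
          expression = c(draw(mu_mut), draw(mu_wt)),
          stringsAsFactors = FALSE
        )
      }
      rbind(make(paralog_id[i], "paralog", fold, 1),
            make(paste0("ctrl_unrelated_", gene_id[i]), "unrelated", 1, 1),
            make(paste0("ctrl_remote_", gene_id[i]), "remote", 1, 1))
    })
    knockout <- do.call(rbind, rows)
  }

  truth_genes <- data.frame(
    gene_id = gene_id, branch = branch, essential = essential,
    mechanism = mechanism, paralog_id = paralog_id, similarity = similarity,
    compensating = !is.na(similarity) & similarity >= cfg$compensation_similarity,
    stringsAsFactors = FALSE
  )
  truth_lines <- data.frame(
    line_id = screens[[1]]$line_id, gene_id = gene_id,
    true_efficiency = efficiency, artifact_40d3 = artifact,
    off_target = det$off_target, true_lethal_state = det$state | artifact,
    stringsAsFactors = FALSE
  )

  structure(
    list(config = cfg, tree = ape::write.tree(tr$phylo), focal = tr$focal,
         presence = presence, annotations = annotations, screens = screens,
         qpcr = qpcr, knockout = knockout,
         truth_genes = truth_genes, truth_lines = truth_lines),
    class = "synthetic_bundle"
  )
}

#' Simulate qPCR Ct wells for a known knockdown efficiency
#'
#' Inverse of the delta-delta-Ct transform: builds target and reference Ct
#' wells for knockdown and control conditions such that, with zero noise,
#' [relative_expression()] recovers the input efficiency exactly. The
#' target's knockdown Ct is shifted by `-log2(efficiency / 100)` cycles
#' relative to its control baseline; the reference gene is unshifted.
#'
#' @param efficiency True percent-of-control in (0, 200].
#' @param n_reps Replicate wells per (role, condition) cell.
#' @param noise_sd Per-well Gaussian Ct noise SD (cycles).
#' @param seed Optional integer seed.
#' @param base_ct_target,base_ct_reference Baseline Ct values (cycles).
#' @return Data.frame of wells: `gene_role`, `condition`, `replicate`,
#'   `ct`.
#' @examples
#' w <- simulate_qpcr(25, n_reps = 3, noise_sd = 0)
#' relative_expression(w)$percent_of_control
#' @export
simulate_qpcr <- function(efficiency, n_reps = 3, noise_sd = 0, seed = NULL,
                          base_ct_target = 20, base_ct_reference = 15) {
  abort_if(!is.numeric(efficiency) || efficiency <= 0 || efficiency > 200,
           "efficiency must lie in (0, 200]")
  abort_if(!is_count(n_reps) || n_reps < 1, "n_reps must be a positive integer")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  shift <- -log2(efficiency / 100)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      gene_role = c("target", "reference"),
                      condition = c("knockdown", "control"),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$gene_role == "target", base_ct_target, base_ct_reference)
  base <- base + ifelse(grid$gene_role == "target" & grid$condition == "knockdown",
                        shift, 0)
  ct <- with_seed(seed, base + stats::rnorm(nrow(grid), 0, noise_sd))
  data.frame(gene_role = grid$gene_role, condition = grid$condition,
             replicate = grid$replicate, ct = ct, stringsAsFactors = FALSE)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("synthetic_bundle: %d genes, %d screen replicate(s), seed %d\n",
              nrow(x$truth_genes), length(x$screens), x$config$seed))
  invisible(x)
}
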