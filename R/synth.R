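#' Specification for a synthetic two-condition expression experiment
#'
#' Describes the planted structure of a synthetic bulk RNA-seq experiment:
#' a two-condition design (non-receptive vs receptive, by default labelled
#' `day3`/`day4`) with a chosen number of planted up- and down-regulated
#' genes at a given mean absolute log2 effect and log-scale noise.
#'
#' @param seed Integer seed; every generated value is a pure function of the
#'   spec including this seed.
#' @param n_genes Total number of genes.
#' @param n_up,n_down Numbers of planted up-/down-regulated genes
#'   (`n_up + n_down <= n_genes`).
#' @param log2_effect Mean planted absolute log2 fold change (default 2).
#' @param reps_per_condition Biological replicates per condition (default 3).
#' @param noise_sd Per-sample noise SD on the log2 scale (default 0.25).
#' @param conditions Two condition labels, baseline first.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed, n_genes, n_up, n_down, log2_effect = 2,
                       reps_per_condition = 3L, noise_sd = 0.25,
                       conditions = c("day3", "day4")) {
  if (n_up + n_down > n_genes) abort("n_up + n_down must be <= n_genes")
  if (reps_per_condition < 2L) abort("reps_per_condition must be >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (length(conditions) != 2L || conditions[1] == conditions[2]) {
    abort("conditions must be two distinct labels")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_up = as.integer(n_up), n_down = as.integer(n_down),
         log2_effect = log2_effect,
         reps_per_condition = as.integer(reps_per_condition),
         noise_sd = noise_sd, conditions = conditions),
    class = "synth_spec"
  )
}

#' Generate a synthetic expression matrix with planted DE genes
#'
#' Baseline log2 means are drawn uniformly on \[3, 10\]; planted genes are
#' shifted by +/- `log2_effect` in the second condition; each sample value is
#' `2^(mean + Normal(0, noise_sd))`. Which genes are planted is randomized.
#'
#' @param spec A [synth_spec()].
#' @return List with `expression` (an `expression_matrix`), `truth` (tibble of
#'   `gene_id` and planted `direction`: up/down/unchanged) and `spec`. The
#'   seed is recorded as an attribute on the expression matrix.
#' @examples
#' b <- gen_expression(synth_spec(1, 100, 10, 10))
#' table(b$truth$direction)
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_offset_seed(spec$seed, 101L, {
    n <- spec$n_genes
    r <- spec$reps_per_condition
    ids <- synth_gene_ids(n)
    planted <- sample.int(n, spec$n_up + spec$n_down)
    up_idx <- planted[seq_len(spec$n_up)]
    down_idx <- setdiff(planted, up_idx)
    base <- runif(n, 3, 10)
    shift <- numeric(n)
    shift[up_idx] <- spec$log2_effect
    shift[down_idx] <- -spec$log2_effect
    samples <- c(paste0(spec$conditions[1], "_r", seq_len(r)),
                 paste0(spec$conditions[2], "_r", seq_len(r)))
    cond <- stats::setNames(rep(spec$conditions, each = r), samples)
    mu <- cbind(matrix(base, n, r), matrix(base + shift, n, r))
    vals <- 2^(mu + matrix(rnorm(n * 2 * r, 0, spec$noise_sd), n, 2 * r))
    colnames(vals) <- samples
    expr <- new_expression_matrix(
      tibble::tibble(gene_id = ids, !!!as.data.frame(vals)), cond
    )
    attr(expr, "seed") <- spec$seed
    truth <- tibble::tibble(
      gene_id = ids,
      direction = dplyr::case_when(
        seq_len(n) %in% up_idx ~ "up",
        seq_len(n) %in% down_idx ~ "down",
        TRUE ~ "unchanged"
      )
    )
    list(expression = expr, truth = truth, spec = spec)
  })
}

#' Generate synthetic promoters with planted motif instances
#'
#' Background bases are i.i.d. uniform over A,C,G,T. Each target gene's
#' promoter receives `sites_per_target` non-overlapping motif instances at
#' random positions on a random strand. Instances are sampled per column from
#' the PWM's frequency distribution, or fixed to the consensus with
#' `consensus_only = TRUE` (which makes the relative score exactly 1).
#'
#' @param n_genes Number of promoters to generate (gene ids `g0001...`).
#' @param length Promoter length in bp (default 1000, i.e. 1 kb upstream).
#' @param pwm A `pwm` object, or `NULL` for pure background.
#' @param target_genes Character vector of gene ids to receive planted sites;
#'   must be a subset of the generated ids.
#' @param sites_per_target Number of planted instances per target promoter.
#' @param seed Integer seed.
#' @param consensus_only Plant the per-column argmax sequence instead of
#'   sampling from the column distributions.
#' @return A `promoter_set`; planted instances are recorded in the
#'   `planted_sites` attribute (tibble of `gene_id`, `position`, `strand`).
#' @export
gen_promoters <- function(n_genes, length = 1000L, pwm = NULL,
                          target_genes = character(0), sites_per_target = 1L,
                          seed = 1L, consensus_only = FALSE) {
  ids <- synth_gene_ids(n_genes)
  if (!all(target_genes %in% ids)) {
    abort("target_genes must be a subset of the generated gene ids")
  }
  if (!is.null(pwm) && ncol(pwm$matrix) > length) {
    abort("PWM is longer than the promoter")
  }
  bases <- c("A", "C", "G", "T")
  with_offset_seed(seed, 202L, {
    seqs <- vapply(seq_len(n_genes), function(i) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
    sites <- NULL
    if (!is.null(pwm) && length(target_genes) > 0L && sites_per_target > 0L) {
      L <- ncol(pwm$matrix)
      freq <- sweep(pwm$matrix, 2, colSums(pwm$matrix), "/")
      sites <- purrr::map(target_genes, function(g) {
        placed <- integer(0)
        strands <- character(0)
        for (s in seq_len(sites_per_target)) {
          ok <- FALSE
          for (attempt in seq_len(1000L)) {
            pos <- sample.int(length - L + 1L, 1L)
            if (all(abs(pos - placed) >= L)) { ok <- TRUE; break }
          }
          if (!ok) abort("could not place non-overlapping motif instances")
          placed <- c(placed, pos)
          strands <- c(strands, sample(c("+", "-"), 1L))
        }
        inst <- vapply(seq_along(placed), function(k) {
          letters_ <- if (consensus_only) {
            bases[apply(freq, 2, which.max)]
          } else {
            vapply(seq_len(L), function(j) sample(bases, 1L, prob = freq[, j]),
                   character(1))
          }
          s <- paste(letters_, collapse = "")
          if (strands[k] == "-") s <- revcomp(s)
          s
        }, character(1))
        list(gene = g, pos = placed, strand = strands, inst = inst)
      })
      for (st in sites) {
        i <- match(st$gene, ids)
        for (k in seq_along(st$pos)) {
          substr(seqs[i], st$pos[k], st$pos[k] + nchar(st$inst[k]) - 1L) <- st$inst[k]
        }
      }
    }
    out <- new_promoter_set(tibble::tibble(gene_id = ids, sequence = seqs))
    if (!is.null(sites)) {
      attr(out, "planted_sites") <- dplyr::bind_rows(purrr::map(sites, function(st) {
        tibble::tibble(gene_id = st$gene, position = st$pos, strand = st$strand)
      }))
    }
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Generate a scale-free interaction network by preferential attachment
#'
#' Starts from `m_attach` edgeless seed nodes; the first added node attaches
#' to all of them, and every later node attaches to `m_attach` distinct
#' existing nodes with probability proportional to current degree, so the
#' result has exactly `m_attach * (n_nodes - m_attach)` edges and is
#' connected. Combined scores are drawn uniformly on \[0.4, 1\].
#'
#' @param n_nodes Number of nodes (> `m_attach`).
#' @param m_attach Edges added per new node (>= 1).
#' @param seed Integer seed.
#' @return An `interaction_edges` tibble (`node_a`, `node_b`,
#'   `combined_score`).
#' @export
gen_network <- function(n_nodes, m_attach = 2L, seed = 1L) {
  n_nodes <- as.integer(n_nodes); m_attach <- as.integer(m_attach)
  if (!(n_nodes > m_attach && m_attach >= 1L)) {
    abort("need n_nodes > m_attach >= 1")
  }
  with_offset_seed(seed, 303L, {
    deg <- integer(n_nodes)
    from <- integer(0); to <- integer(0)
    for (v in (m_attach + 1L):n_nodes) {
      existing <- seq_len(v - 1L)
      targets <- if (all(deg[existing] == 0L)) {
        existing  # first added node: all seed nodes (degrees are tied at 0)
      } else {
        sample(existing, m_attach, prob = deg[existing])
      }
      from <- c(from, rep(v, length(targets)))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- deg[v] + length(targets)
    }
    ids <- sprintf("n%03d", seq_len(n_nodes))
    new_interaction_edges(tibble::tibble(
      node_a = ids[from], node_b = ids[to],
      combined_score = runif(length(from), 0.4, 1)
    ))
  })
}

#' Generate ranked drug reference profiles with one planted reverser
#'
#' Every drug ranks the gene universe from most up-regulated (rank 1) to most
#' down-regulated (rank n) by an i.i.d. Uniform(0,1) score. The planted
#' reverser additionally shifts the query's `down_set` genes up and its
#' `up_set` genes down by `effect`, displacing them by about
#' `effect * n_genes` rank positions, so it reverses the query signature.
#' With `effect = 1` every `down_set` gene ranks strictly above every other
#' gene.
#'
#' @param n_drugs Number of drugs (`drug_01`, `drug_02`, ...).
#' @param n_genes Size of the ranked gene universe (ids `g0001...`).
#' @param up_set,down_set Disjoint query gene sets (subsets of the universe).
#' @param reverser_id Which drug id gets the planted reversal.
#' @param effect Displacement fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `ranked_profiles` tibble (`drug_id`, `rank`, `gene_id`).
#' @export
gen_drug_profiles <- function(n_drugs, n_genes, up_set, down_set, reverser_id,
                              effect = 0.8, seed = 1L) {
  if (length(intersect(up_set, down_set)) > 0L) {
    abort("up_set and down_set must be disjoint")
  }
  ids <- synth_gene_ids(n_genes)
  if (!all(c(up_set, down_set) %in% ids)) {
    abort("query sets must be subsets of the gene universe")
  }
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  if (!reverser_id %in% drugs) abort("reverser_id must be one of the generated drug ids")
  if (!(effect > 0 && effect <= 1)) abort("effect must lie in (0, 1]")
  with_offset_seed(seed, 404L, {
    dplyr::bind_rows(purrr::map(drugs, function(d) {
      score <- runif(n_genes)
      if (d == reverser_id) {
        score[ids %in% down_set] <- score[ids %in% down_set] + effect
        score[ids %in% up_set] <- score[ids %in% up_set] - effect
      }
      ord <- order(score, decreasing = TRUE)
      tibble::tibble(drug_id = d, rank = seq_len(n_genes), gene_id = ids[ord])
    })) |> validate_ranked_profiles()
  })
}

#' Generate paired mouse/human DE tables with planted concordance structure
#'
#' Builds differential-expression tables for two species whose shared
#' (orthologous) DE genes fall into four planted concordance categories, plus
#' species-exclusive DE genes, mirroring a cross-species Venn comparison.
#'
#' @param n_shared Number of ortholog pairs DE in both species; must equal the
#'   sum of the four category counts.
#' @param n_consistent_down,n_consistent_up Pairs down-/up-regulated in both.
#' @param n_mdown_hup Pairs down in mouse, up in human.
#' @param n_mup_hdown Pairs up in mouse, down in human.
#' @param n_mouse_only,n_human_only Species-exclusive DE gene counts.
#' @param seed Integer seed.
#' @return List with `mouse_de`, `human_de` (tibbles of `gene_id`, `log2fc`,
#'   `p_value`), one-to-one `orthologs` (`mouse_gene`, `human_gene`) and
#'   `truth` (per-pair planted category).
#' @export
gen_species_pair <- function(n_shared, n_consistent_down, n_consistent_up,
                             n_mdown_hup, n_mup_hdown,
                             n_mouse_only, n_human_only, seed = 1L) {
  counts <- c(n_consistent_down, n_consistent_up, n_mdown_hup, n_mup_hdown)
  if (n_shared != sum(counts)) {
    abort("n_shared must equal the sum of the four category counts")
  }
  with_offset_seed(seed, 505L, {
    cat_names <- c("consistent_down", "consistent_up",
                   "mouse_down_human_up", "mouse_up_human_down")
    category <- rep(cat_names, counts)
    m_sign <- ifelse(category %in% c("consistent_down", "mouse_down_human_up"), -1, 1)
    h_sign <- ifelse(category %in% c("consistent_down", "mouse_up_human_down"), -1, 1)
    n_m <- n_shared + n_mouse_only
    n_h <- n_shared + n_human_only
    mouse_genes <- sprintf("mgene%05d", seq_len(n_m))
    human_genes <- sprintf("hgene%05d", seq_len(n_h + n_mouse_only))
    # shared pairs use the first n_shared ids of each species; mouse-only DE
    # genes map to human genes that are NOT in the human DE table
    orthologs <- tibble::tibble(
      mouse_gene = mouse_genes,
      human_gene = c(human_genes[seq_len(n_shared)],
                     human_genes[n_h + seq_len(n_mouse_only)])
    )
    mouse_de <- tibble::tibble(
      gene_id = mouse_genes,
      log2fc = c(m_sign * runif(n_shared, 1, 4),
                 sample(c(-1, 1), n_mouse_only, TRUE) * runif(n_mouse_only, 1, 4)),
      p_value = runif(n_m, 1e-6, 0.05)
    )
    human_de <- tibble::tibble(
      gene_id = human_genes[seq_len(n_h)],
      log2fc = c(h_sign * runif(n_shared, 1, 4),
                 sample(c(-1, 1), n_human_only, TRUE) * runif(n_human_only, 1, 4)),
      p_value = runif(n_h, 1e-6, 0.05)
    )
    truth <- tibble::tibble(
      mouse_gene = mouse_genes[seq_len(n_shared)],
      human_gene = human_genes[seq_len(n_shared)],
      category = category
    )
    list(mouse_de = mouse_de, human_de = human_de,
         orthologs = orthologs, truth = truth)
  })
}

#' Generate synthetic qPCR Ct values consistent with given fold changes
#'
#' The reference gene's Ct is constant at `base_ct` in every sample. Each
#' target gene gets a random baseline Ct in condition A; in condition B its
#' Ct is lowered by `log2(fold_change)` (higher expression, earlier cycle).
#' Per-well Normal(0, `noise_sd`) noise is added to target wells.
#'
#' @param fold_changes Named positive numeric vector: gene id -> planted fold
#'   change (condition B over A).
#' @param ref_gene Reference gene id (default `"Rpl7"`).
#' @param base_ct Reference Ct in cycles (default 16).
#' @param noise_sd Per-well Ct noise SD (default 0.1; 0 gives exact recovery).
#' @param reps_per_condition Samples per condition (default 3).
#' @param conditions Two condition labels, baseline first.
#' @param seed Integer seed.
#' @return Tibble with columns `sample_id`, `condition`, `gene_id`, `ct`,
#'   carrying `ref_gene` as an attribute.
#' @export
gen_ct_values <- function(fold_changes, ref_gene = "Rpl7", base_ct = 16,
                          noise_sd = 0.1, reps_per_condition = 3L,
                          conditions = c("day3", "day4"), seed = 1L) {
  if (any(fold_changes <= 0)) abort("fold changes must be positive")
  if (is.null(names(fold_changes)) || anyDuplicated(names(fold_changes))) {
    abort("fold_changes must be uniquely named by gene id")
  }
  with_offset_seed(seed, 606L, {
    genes <- names(fold_changes)
    samples <- tibble::tibble(
      sample_id = c(paste0(conditions[1], "_s", seq_len(reps_per_condition)),
                    paste0(conditions[2], "_s", seq_len(reps_per_condition))),
      condition = rep(conditions, each = reps_per_condition)
    )
    base_a <- stats::setNames(runif(length(genes), 22, 30), genes)
    grid <- tidyr::expand_grid(samples, gene_id = genes)
    grid$ct <- unname(
      base_a[grid$gene_id] -
        ifelse(grid$condition == conditions[2],
               log2(fold_changes[grid$gene_id]), 0) +
        rnorm(nrow(grid), 0, noise_sd)
    )
    ref <- dplyr::mutate(samples, gene_id = ref_gene, ct = base_ct)
    out <- dplyr::bind_rows(ref, grid)
    attr(out, "ref_gene") <- ref_gene
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Generate the full synthetic input bundle for a pipeline run
#'
#' Convenience wrapper tying all generators together under one seed with
#' per-component sub-streams: expression with planted DE, promoters with a
#' motif planted in part of the up-regulated set, a scale-free network, drug
#' profiles with a planted reverser, a cross-species pair and a Ct table.
#'
#' @param seed Integer master seed.
#' @param n_genes,n_up,n_down Expression design (defaults 1000/316/225).
#' @param n_drugs Number of drug profiles (default 50).
#' @return Named list of all generated components plus their truth records.
#' @export
gen_bundle <- function(seed = 1L, n_genes = 1000L, n_up = 316L, n_down = 225L,
                       n_drugs = 50L) {
  spec <- synth_spec(seed, n_genes, n_up, n_down)
  expr <- gen_expression(spec)
  up_genes <- expr$truth$gene_id[expr$truth$direction == "up"]
  down_genes <- expr$truth$gene_id[expr$truth$direction == "down"]
  pwm <- example_pwm()
  tf_targets <- head(up_genes, max(1L, floor(0.8 * min(50L, length(up_genes)))))
  promoters <- gen_promoters(n_genes, 1000L, pwm, tf_targets,
                             sites_per_target = 2L, seed = seed)
  network <- gen_network(289L, 2L, seed = seed)
  profiles <- gen_drug_profiles(n_drugs, n_genes, up_genes, down_genes,
                                reverser_id = "drug_01", effect = 0.8,
                                seed = seed)
  species <- gen_species_pair(115L, 25L, 50L, 20L, 20L, 426L, 1994L, seed = seed)
  qpcr_genes <- c(head(up_genes, 5L), head(down_genes, 5L))
  planted_fc <- stats::setNames(
    2^(ifelse(seq_along(qpcr_genes) <= 5L, spec$log2_effect, -spec$log2_effect)),
    qpcr_genes
  )
  ct <- gen_ct_values(planted_fc, seed = seed)
  list(seed = as.integer(seed), spec = spec, expression = expr$expression,
       truth = expr$truth, pwm = pwm, promoters = promoters,
       tf_targets = tf_targets, network = network, profiles = profiles,
       reverser_id = "drug_01", species = species, ct = ct,
       planted_fc = planted_fc)
}

#' A small high-information example PWM
#'
#' An 8-position counts matrix with a strong non-palindromic consensus
#' (`GGATTACA`), used in examples and as the planted motif of
#' [gen_bundle()]. Being non-palindromic, its forward and reverse-complement
#' hits are distinguishable in strand-aware scans.
#' @return A `pwm` object.
#' @export
example_pwm <- function() {
  cons <- c("G", "G", "A", "T", "T", "A", "C", "A")
  m <- matrix(1, 4, length(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 18
  new_pwm("TF_ACGT", m)
}

# reverse complement of an A/C/G/T/N string
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}
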