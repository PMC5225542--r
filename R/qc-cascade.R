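#' Quality-control thresholds
#'
#' Default thresholds follow the marker-filtering protocol the package
#' reproduces: call rate >= 65%, PIC >= 1%, MAF >= 2%, repeatability
#' >= 95%, Hardy-Weinberg testing with a 10,000-step Markov chain after
#' 100,000 dememorisations, and genotypic LD significance at p < 0.0001.
#'
#' @param call_rate_min,pic_min,maf_min,repeatability_min Retention
#'   thresholds (fractions in `[0, 1]`).
#' @param hwe_alpha False-discovery-rate level for the Hardy-Weinberg
#'   step (Benjamini-Hochberg across loci, within each population).
#' @param hwe_min_pops A locus is removed when significant in at least
#'   this many populations; `NULL` means all populations.
#' @param hwe_chain_steps,hwe_dememorisations Markov-chain configuration
#'   for loci too large to enumerate.
#' @param ld_alpha Significance level for the genotypic LD test.
#' @param ld_permutations Permutations per LD test.
#' @param ld_max_pairs Cap on the number of locus pairs screened for LD;
#'   when the number of pairs exceeds the cap a seeded random sample of
#'   pairs is tested.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate_min = 0.65, pic_min = 0.01, maf_min = 0.02,
                          repeatability_min = 0.95,
                          hwe_alpha = 0.05, hwe_min_pops = NULL,
                          hwe_chain_steps = 10000, hwe_dememorisations = 100000,
                          ld_alpha = 1e-4, ld_permutations = 10000,
                          ld_max_pairs = 1e5) {
  th <- list(call_rate_min = call_rate_min, pic_min = pic_min,
             maf_min = maf_min, repeatability_min = repeatability_min,
             hwe_alpha = hwe_alpha, hwe_min_pops = hwe_min_pops,
             hwe_chain_steps = hwe_chain_steps,
             hwe_dememorisations = hwe_dememorisations,
             ld_alpha = ld_alpha, ld_permutations = ld_permutations,
             ld_max_pairs = ld_max_pairs)
  for (f in c("call_rate_min", "pic_min", "maf_min", "repeatability_min",
              "hwe_alpha", "ld_alpha")) {
    if (th[[f]] < 0 || th[[f]] > 1) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  structure(th, class = "qc_thresholds")
}

new_filter_ledger <- function() {
  tibble::tibble(step = character(), loci_in = integer(),
                 loci_removed = integer(), loci_out = integer())
}

ledger_add <- function(ledger, step, loci_in, loci_removed) {
  dplyr::bind_rows(ledger, tibble::tibble(
    step = step, loci_in = as.integer(loci_in),
    loci_removed = as.integer(loci_removed),
    loci_out = as.integer(loci_in - loci_removed)))
}

#' Check the conservation invariant of a filter ledger
#'
#' Every step must satisfy `loci_out = loci_in - loci_removed` and chain
#' onto the previous step's output.
#'
#' @param ledger A filter-ledger tibble (`step`, `loci_in`,
#'   `loci_removed`, `loci_out`).
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_ledger <- function(ledger) {
  if (!all(ledger$loci_out == ledger$loci_in - ledger$loci_removed)) {
    stop("ledger violates loci_out = loci_in - loci_removed", call. = FALSE)
  }
  if (nrow(ledger) > 1 &&
      !all(ledger$loci_in[-1] == ledger$loci_out[-nrow(ledger)])) {
    stop("ledger steps do not chain", call. = FALSE)
  }
  invisible(TRUE)
}

#' Retain one SNP per clone
#'
#' DArT calls several SNPs on one sequence cluster (clone); a single,
#' highly informative SNP is kept per clone id: highest call rate, ties
#' broken by highest MAF, remaining ties by lowest input position.
#'
#' @param G A [geno_matrix()] whose locus table carries `clone_id`.
#' @return A list with the de-duplicated `genotypes`, the one-step
#'   `ledger`, and `removed` (tibble of removed loci).
#' @export
dedupe_clones <- function(G) {
  if (all(is.na(G$loci$clone_id))) {
    stop("no clone metadata present; skip the de-duplication step explicitly",
         call. = FALSE)
  }
  m <- locus_metrics(G)
  clone <- ifelse(is.na(G$loci$clone_id),
                  paste0(".singleton_", seq_len(nrow(G$loci))),
                  G$loci$clone_id)
  ord <- order(clone, -m$call_rate, -m$maf, seq_along(clone))
  keep_idx <- ord[!duplicated(clone[ord])]
  keep <- sort(keep_idx)
  removed <- setdiff(seq_along(clone), keep)
  list(genotypes = geno_subset(G, loc = keep),
       ledger = ledger_add(new_filter_ledger(), "clone_dedupe",
                           ncol(G$scores), length(removed)),
       removed = tibble::tibble(locus = colnames(G$scores)[removed],
                                step = "clone_dedupe"))
}

#' The marker-filtering cascade
#'
#' Applies, in order: clone de-duplication, the call-rate / PIC / MAF /
#' repeatability thresholds, removal of loci deviating from
#' Hardy-Weinberg equilibrium (exact test per population,
#' Benjamini-Hochberg control across loci, removed when significant in at
#' least `hwe_min_pops` populations), removal of monomorphic loci, and
#' pruning of one locus from each significantly linked pair (the member
#' with the lower call rate, ties to the higher input position). Every
#' step is recorded in an accounting ledger satisfying
#' `loci_in = loci_removed + loci_out`.
#'
#' @param G A [geno_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param replicate_pairs Optional replicate pairing for repeatability
#'   (see [locus_metrics()]). Replicate individuals are removed from the
#'   output matrix after the repeatability step.
#' @param map Optional [pop_map()]; when supplied the HWE test runs per
#'   population, otherwise on the pooled individuals.
#' @param seed Integer seed driving the Monte-Carlo HWE/LD streams.
#' @param dedupe Set `FALSE` to skip clone de-duplication (matrices
#'   without clone metadata).
#' @param ld Set `FALSE` to skip the LD step.
#' @return A list with `genotypes` (filtered [geno_matrix()]), `ledger`
#'   (the accounting tibble, class `filter_ledger`), and `removed`
#'   (locus, step) with reason codes.
#' @export
filter_cascade <- function(G, thresholds = qc_thresholds(),
                           replicate_pairs = NULL, map = NULL,
                           seed = 1L, dedupe = TRUE, ld = TRUE) {
  set.seed(seed)
  removed_all <- tibble::tibble(locus = character(), step = character())
  if (dedupe) {
    dd <- dedupe_clones(G)
    G <- dd$genotypes
    ledger <- dd$ledger
    removed_all <- dplyr::bind_rows(removed_all, dd$removed)
  } else {
    ledger <- new_filter_ledger()
  }

  drop_step <- function(G, bad, step) {
    ledger <<- ledger_add(ledger, step, ncol(G$scores), sum(bad))
    if (any(bad)) {
      removed_all <<- dplyr::bind_rows(
        removed_all, tibble::tibble(locus = colnames(G$scores)[bad], step = step))
      G <- geno_subset(G, loc = !bad)
    }
    if (ncol(G$scores) == 0) warning("no loci left after step ", step)
    G
  }

  m <- locus_metrics(G, replicate_pairs)
  G <- drop_step(G, m$call_rate < thresholds$call_rate_min, "call_rate")
  m <- m[match(colnames(G$scores), m$locus), ]
  G <- drop_step(G, m$pic < thresholds$pic_min, "pic")
  m <- m[match(colnames(G$scores), m$locus), ]
  G <- drop_step(G, m$maf < thresholds$maf_min, "maf")
  m <- m[match(colnames(G$scores), m$locus), ]
  rep_ok <- is.na(m$repeatability) | m$repeatability >= thresholds$repeatability_min
  G <- drop_step(G, !rep_ok, "repeatability")

  # replicate individuals have served their purpose
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0) {
    G <- drop_replicates(G, replicate_pairs)
  }

  # Hardy-Weinberg per population, BH across loci
  if (ncol(G$scores) > 0) {
    pops <- if (is.null(map)) factor(rep("all", nrow(G$scores)))
            else map_factor(G, map)
    sig <- matrix(FALSE, ncol(G$scores), nlevels(pops))
    for (k in seq_len(nlevels(pops))) {
      s <- G$scores[pops == levels(pops)[k], , drop = FALSE]
      n_aa <- colSums(s == 0L, na.rm = TRUE)
      n_ab <- colSums(s == 2L, na.rm = TRUE)
      n_bb <- colSums(s == 1L, na.rm = TRUE)
      p <- hwe_enum_vec(n_aa, n_ab, n_bb)
      sig[, k] <- stats::p.adjust(p, "BH") < thresholds$hwe_alpha
    }
    need <- if (is.null(thresholds$hwe_min_pops)) nlevels(pops)
            else min(thresholds$hwe_min_pops, nlevels(pops))
    G <- drop_step(G, rowSums(sig) >= need, "hwe")
  }

  m <- locus_metrics(G)
  G <- drop_step(G, m$monomorphic, "monomorphic")

  if (ld && ncol(G$scores) > 1) {
    L <- ncol(G$scores)
    n_pairs <- L * (L - 1) / 2
    if (n_pairs <= thresholds$ld_max_pairs) {
      pairs <- utils::combn(L, 2)
    } else {
      i <- sample.int(L, thresholds$ld_max_pairs, replace = TRUE)
      j <- sample.int(L - 1, thresholds$ld_max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      pairs <- unique(rbind(pmin(i, j), pmax(i, j)), MARGIN = 2)
    }
    m <- locus_metrics(G)
    flag <- rep(FALSE, L)
    for (c in seq_len(ncol(pairs))) {
      i <- pairs[1, c]; j <- pairs[2, c]
      if (flag[i] || flag[j]) next
      r <- genotypic_ld_test(G$scores[, i], G$scores[, j],
                             n_permutations = thresholds$ld_permutations)
      if (!r$skipped && r$p_value < thresholds$ld_alpha) {
        # remove the lower-call-rate member; tie -> higher index
        drop <- if (m$call_rate[i] < m$call_rate[j]) i
                else if (m$call_rate[j] < m$call_rate[i]) j
                else max(i, j)
        flag[drop] <- TRUE
      }
    }
    G <- drop_step(G, flag, "ld")
  } else {
    ledger <- ledger_add(ledger, "ld", ncol(G$scores), 0)
  }

  class(ledger) <- c("filter_ledger", class(ledger))
  validate_ledger(ledger)
  list(genotypes = G, ledger = ledger, removed = removed_all)
}
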