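# Gene-set overlap analyses and over-representation testing.

#' Exact Venn partition of named gene sets
#'
#' Partitions the union of 2-5 named sets into the `2^n - 1` disjoint
#' Venn regions (every gene falls in exactly one region) and exposes the
#' usual convenience intersections (all pairwise, and the all-way
#' intersection).
#'
#' @param sets Named list of 2-5 character vectors of gene ids
#'   (duplicates within a set are collapsed).
#' @return Object of class `overlap_report`: list with
#'   * `regions`: `data.frame` (`region` e.g. `"A&B"`, `code` e.g.
#'     `"110"`, `count`),
#'   * `memberships`: list of gene vectors per region code,
#'   * `intersections`: named list (pairwise and all-way) of gene vectors,
#'   * `set_sizes`, `union_size`.
#' @examples
#' venn_partition(list(A = c("a", "b"), B = c("b", "c"), C = c("b", "d")))
#' @export
venn_partition <- function(sets) {
  assert_that(is.list(sets) && length(sets) >= 2 && length(sets) <= 5,
              "need 2 to 5 named sets (got %d); use a membership table beyond 5",
              length(sets))
  assert_that(!is.null(names(sets)) && all(nzchar(names(sets))), "sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  n <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- matrix(FALSE, nrow = length(universe), ncol = n)
  for (j in seq_len(n)) member[, j] <- universe %in% sets[[j]]
  code <- vapply(seq_along(universe),
                 function(i) paste(as.integer(member[i, ]), collapse = ""),
                 character(1))

  combos <- expand.grid(rep(list(c(TRUE, FALSE)), n))[, n:1, drop = FALSE]
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  codes_all <- apply(combos, 1L, function(m) paste(as.integer(m), collapse = ""))
  region_name <- apply(combos, 1L, function(m) paste(names(sets)[as.logical(m)], collapse = "&"))
  memberships <- lapply(codes_all, function(cc) universe[code == cc])
  names(memberships) <- codes_all
  regions <- data.frame(region = region_name, code = codes_all,
                        count = lengths(memberships),
                        row.names = NULL, stringsAsFactors = FALSE)

  inter <- list()
  if (n > 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      inter[[paste(names(sets)[c(i, j)], collapse = "&")]] <-
        intersect(sets[[i]], sets[[j]])
    }
  }
  inter[[paste(names(sets), collapse = "&")]] <- Reduce(intersect, sets)

  out <- list(regions = regions, memberships = memberships,
              intersections = inter,
              set_sizes = lengths(sets), union_size = length(universe))
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Venn partition of %d sets (union: %d genes)\n",
              length(x$set_sizes), x$union_size))
  print(x$regions[order(-x$regions$count), c("region", "count")], row.names = FALSE)
  invisible(x)
}

#' Hypergeometric over-representation test of a gene set
#'
#' For each pathway, tests whether the study set contains more pathway
#' members than expected by drawing `n = |set|` genes from the universe
#' without replacement: the one-sided upper-tail hypergeometric
#' probability `P(X >= k)` with `K` pathway members among `N` universe
#' genes. P-values are BH-adjusted across pathways and results sorted by
#' p. This is the standard over-representation construction (equivalent
#' to a one-tailed Fisher exact test on the 2x2 table).
#'
#' Genes outside the universe (in the set or the map) are dropped with a
#' warning, not an error.
#'
#' @param set Character vector of gene ids (the study set).
#' @param universe Character vector of background gene ids (e.g. all
#'   detected genes).
#' @param pathway_map `data.frame` with columns `gene`, `pathway`.
#' @return `data.frame` with columns `pathway, k, n, K, N, p, fdr`,
#'   sorted by `p`.
#' @examples
#' map <- data.frame(gene = c("g1", "g2", "g3", "g4"), pathway = "pw1")
#' enrich(c("g1", "g2", "g3", "g4", "g9"), paste0("g", 1:10), map)
#' @export
enrich <- function(set, universe, pathway_map) {
  assert_that(length(set) > 0 && length(universe) > 0,
              "set and universe must be non-empty")
  assert_that(is.data.frame(pathway_map) &&
                all(c("gene", "pathway") %in% names(pathway_map)),
              "pathway_map needs columns gene and pathway")
  universe <- unique(as.character(universe))
  set <- unique(as.character(set))
  stray <- setdiff(set, universe)
  if (length(stray)) {
    warning(sprintf("%d set gene(s) outside the universe dropped", length(stray)))
    set <- intersect(set, universe)
  }
  map <- pathway_map[pathway_map$gene %in% universe, , drop = FALSE]
  if (nrow(map) < nrow(pathway_map)) {
    warning(sprintf("%d pathway annotation(s) outside the universe dropped",
                    nrow(pathway_map) - nrow(map)))
  }
  assert_that(length(set) > 0, "no set gene remains inside the universe")
  N <- length(universe); n <- length(set)
  by_pw <- split(unique(map[c("gene", "pathway")])$gene,
                 unique(map[c("gene", "pathway")])$pathway)
  res <- lapply(names(by_pw), function(pw) {
    members <- by_pw[[pw]]
    K <- length(members)
    k <- length(intersect(set, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate DEG, dominance-mode and splice-divergence gene sets
#'
#' Reproduces the set cascade used to nominate heterosis candidate genes:
#' the genes differentially expressed in all three populations
#' (`Common_DEGs`, intersection of the three control-vs-heat DEG sets)
#' are intersected with the over-dominant genes of the heat condition
#' (`H_ODO_NAGs`, label `ODO` in the heat-condition mode calls), and that
#' overlap is further intersected with the hybrid's
#' divergently spliced genes (`SD_DAGs`). All intermediate sets and a
#' three-set Venn partition are returned.
#'
#' @param deg_sets Named list of three character vectors: the DEG gene
#'   ids of each population's control-vs-heat contrast.
#' @param mode_calls Heat-condition mode calls from [classify_matrix()]
#'   (or a `data.frame` with `gene` and `label`).
#' @param splice_genes Character vector of divergently spliced gene ids
#'   in the hybrid.
#' @return List with `common_degs`, `odo_genes`, `common_deg_odo`
#'   (= `Common_DEGs` \eqn{\cap} `H_ODO_NAGs`), `final` (additionally
#'   \eqn{\cap} `SD_DAGs`), their sizes in `sizes`, and `venn`
#'   (an `overlap_report` of the three named sets).
#' @export
integrate_heterosis <- function(deg_sets, mode_calls, splice_genes) {
  assert_that(is.list(deg_sets) && length(deg_sets) == 3,
              "deg_sets must list the three populations' DEG sets")
  if (is.null(names(deg_sets))) names(deg_sets) <- c("P1_CvsH", "P2_CvsH", "F1_CvsH")
  assert_that(is.data.frame(mode_calls) && all(c("gene", "label") %in% names(mode_calls)),
              "mode_calls must have columns gene and label")
  deg_sets <- lapply(deg_sets, function(s) sort(unique(as.character(s))))
  splice_genes <- sort(unique(as.character(splice_genes)))
  common_degs <- Reduce(intersect, deg_sets)
  odo_genes <- sort(unique(mode_calls$gene[mode_calls$label == "ODO"]))
  common_deg_odo <- intersect(common_degs, odo_genes)
  final <- intersect(common_deg_odo, splice_genes)
  venn <- venn_partition(list(Common_DEGs = common_degs,
                              H_ODO_NAGs = odo_genes,
                              SD_DAGs = splice_genes))
  list(
    common_degs = common_degs,
    odo_genes = odo_genes,
    splice_genes = splice_genes,
    common_deg_odo = common_deg_odo,
    final = final,
    sizes = c(common_degs = length(common_degs),
              odo_genes = length(odo_genes),
              splice_genes = length(splice_genes),
              common_deg_odo = length(common_deg_odo),
              final = length(final)),
    venn = venn
  )
}
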