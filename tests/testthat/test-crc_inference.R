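toy_expr <- function() {
  m <- matrix(c(5, 0.2, 3, 0.5,
                4, 6, 0.1, 2), nrow = 4,
              dimnames = list(c("G1", "G2", "G3", "G4"), c("s1", "s2")))
  m
}

test_that("active genes are thresholded per sample", {
  expr <- toy_expr()
  expect_setequal(active_genes(expr, "s1", -Inf), rownames(expr))
  expect_length(active_genes(expr, "s1", 100), 0L)
  expect_setequal(active_genes(expr, "s1", 1), c("G1", "G3"))
  expect_error(active_genes(expr, "nope", 1), "unknown sample")

  # planted bimodal expression split exactly at the antimode
  set.seed(41)
  on_genes <- sprintf("ON%02d", 1:20)
  off_genes <- sprintf("OFF%02d", 1:20)
  m <- matrix(c(rnorm(20, 8, 0.5), rnorm(20, -2, 0.5)), ncol = 1,
              dimnames = list(c(on_genes, off_genes), "s"))
  expect_setequal(active_genes(m, "s", 3), on_genes)
})

test_that("super-enhancers are assigned to the closest active gene", {
  genes <- tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                          tss = c(5000L, 20000L), is_tf = TRUE)
  inside <- assign_se_to_gene(region_tbl("chr1", 4000L, 6000L), genes)
  expect_equal(inside$assigned_gene, "A")
  expect_equal(inside$tss_distance, 0L)

  near <- assign_se_to_gene(region_tbl("chr1", 6000L, 15000L), genes)
  expect_equal(near$assigned_gene, "A")  # 1 kb beats 5 kb

  off_chrom <- assign_se_to_gene(region_tbl("chr2", 0L, 100L), genes)
  expect_true(is.na(off_chrom$assigned_gene))

  set.seed(42)
  for (rep in 1:100) {
    gn <- tibble::tibble(gene = sprintf("g%02d", 1:8), chrom = "chr1",
                         tss = sample.int(1e5, 8), is_tf = TRUE)
    se <- region_tbl("chr1", s <- sample.int(9e4, 1), s + sample.int(8000, 1))
    got <- assign_se_to_gene(se, gn)
    d <- ifelse(gn$tss >= se$start & gn$tss < se$end, 0L,
                ifelse(gn$tss < se$start, se$start - gn$tss, gn$tss - se$end + 1L))
    best <- gn[order(d, gn$tss, gn$gene), ][1, ]
    expect_equal(got$assigned_gene, best$gene)
  }
})

consensus_motif <- function(consensus, id = "M1", tf = "TFX") {
  ch <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(ch), dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(ch, c("A", "C", "G", "T")), seq_along(ch))] <- 97
  list(motif_id = id, tf_name = tf, counts = counts, pseudocount = 1,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("PWM scanning finds the consensus on both strands at maximal score", {
  m <- consensus_motif("ACGTACGTTG")
  hit <- pwm_scan("ACGTACGTTG", m)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 1L)
  expect_equal(hit$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ACGTACGTTG")))
  hit_rc <- pwm_scan(rc, m)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$score, hit$score)

  expect_equal(nrow(pwm_scan("ACG", m)), 0L)  # shorter than the motif

  # position-by-position scores equal a naive scorer
  set.seed(43)
  lo <- secircuitry:::motif_log_odds(m)
  for (rep in 1:10) {
    s <- random_seq(200)
    fast <- secircuitry:::scan_one_strand(s, lo)
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    naive <- vapply(seq_len(200 - ncol(lo) + 1L), function(p) {
      sum(lo[cbind(codes[p:(p + ncol(lo) - 1L)], seq_len(ncol(lo)))])
    }, numeric(1))
    expect_equal(fast, naive, tolerance = 1e-9)
  }
})

test_that("the TF network has an edge exactly where a motif hits a target's constituents", {
  mA <- consensus_motif("ACGTAACCGGTT", "MA", "A")
  mB <- consensus_motif("TTGGCCAATGCA", "MB", "B")
  seqs <- list(
    A = random_seq(300),
    B = paste0(random_seq(100), "ACGTAACCGGTT", random_seq(100))
  )
  net <- build_tf_network(seqs, list(A = list(mA), B = list(mB)))
  el <- igraph::as_edgelist(net)
  expect_equal(nrow(el), 1L)
  expect_equal(unname(el[1, ]), c("A", "B"))

  empty_net <- build_tf_network(list(A = random_seq(50), B = random_seq(50)),
                                list(A = list(mA), B = list(mB)))
  expect_equal(igraph::ecount(empty_net), 0L)
  expect_message(build_tf_network(seqs, list(A = list(mA))), "without motif")
})

random_directed_graph <- function(n, p_edge = 0.35, p_self = 0.5) {
  adj <- matrix(runif(n * n) < p_edge, n, n,
                dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(adj) <- runif(n) < p_self
  adj
}

graph_from_adj <- function(adj) {
  el <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(nrow(adj), directed = TRUE)
  igraph::V(g)$name <- rownames(adj)
  if (nrow(el)) {
    g <- igraph::add_edges(g, rbind(rownames(adj)[el[, 1]], colnames(adj)[el[, 2]]),
                           weight = 1)
  }
  g
}

test_that("clique enumeration matches exhaustive search and excludes hegemonic nodes", {
  # 3 TFs, all-to-all with self-loops: one clique of size 3
  adj <- matrix(TRUE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- find_crc_cliques(graph_from_adj(adj))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$tfs[[1]], c("A", "B", "C"))

  # a driver with out-edges to everyone but no self-loop and no in-edges
  adj2 <- rbind(cbind(adj, FALSE), TRUE)
  dimnames(adj2) <- list(c("A", "B", "C", "DRV"), c("A", "B", "C", "DRV"))
  adj2["DRV", "DRV"] <- FALSE
  cl2 <- find_crc_cliques(graph_from_adj(adj2))
  expect_false(any(vapply(cl2$tfs, function(x) "DRV" %in% x, logical(1))))
  expect_equal(cl2$tfs[[1]], c("A", "B", "C"))

  set.seed(44)
  for (rep in 1:30) {
    adj <- random_directed_graph(sample(2:8, 1))
    cl <- find_crc_cliques(graph_from_adj(adj), top_k = Inf)
    got <- sort(vapply(cl$tfs, paste, character(1), collapse = ","))
    expect_equal(got, oracle_cliques(adj))
    # post-hoc validator: every reported clique is fully interconnected
    for (tfs in cl$tfs) {
      idx <- match(tfs, rownames(adj))
      expect_true(all(diag(adj)[idx]))
      expect_true(all(adj[idx, idx] & t(adj[idx, idx])))
    }
  }
})

test_that("membership marks a TF present if it appears in any top-k clique", {
  cl_a <- tibble::tibble(rank = 1:2, tfs = list(c("X", "Y"), "Z"),
                         size = c(2L, 1L), score = c(5, 1))
  cl_b <- tibble::tibble(rank = 1L, tfs = list("X"), size = 1L, score = 2)
  m <- crc_membership(list(s1 = cl_a, s2 = cl_b))
  expect_equal(dim(m), c(3L, 2L))
  expect_true(m["Z", "s1"])     # rank-10-style low clique still counts
  expect_false(m["Z", "s2"])
  expect_equal(unname(colSums(m)), c(3L, 1L))
})

test_that("the specificity filter applies the case-min / control-max rule exactly", {
  m <- matrix(FALSE, 2, 10, dimnames = list(c("hi", "lo"),
                                            c(paste0("c", 1:5), paste0("n", 1:5))))
  m["hi", 1:5] <- TRUE
  res <- specificity_filter(m, paste0("c", 1:5), paste0("n", 1:5))
  expect_true(res$is_candidate[res$tf == "hi"])
  expect_false(res$is_candidate[res$tf == "lo"])

  # present in 49% of cases: below the threshold edge
  m2 <- matrix(FALSE, 1, 100 + 10,
               dimnames = list("t", c(paste0("c", 1:100), paste0("n", 1:10))))
  m2["t", 1:49] <- TRUE
  expect_false(specificity_filter(m2, paste0("c", 1:100),
                                  paste0("n", 1:10))$is_candidate)
  m2["t", 50] <- TRUE
  expect_true(specificity_filter(m2, paste0("c", 1:100),
                                 paste0("n", 1:10))$is_candidate)

  expect_error(specificity_filter(m, "c1", "c1"), "overlap")

  set.seed(45)
  for (rep in 1:30) {
    mm <- matrix(runif(5 * 8) < 0.5, 5, 8,
                 dimnames = list(paste0("t", 1:5), paste0("s", 1:8)))
    res <- specificity_filter(mm, paste0("s", 1:5), paste0("s", 6:8),
                              case_min = 0.4, control_max = 0.5)
    for (i in 1:5) {
      cf <- mean(mm[i, 1:5]); nf <- mean(mm[i, 6:8])
      expect_equal(res$is_candidate[res$tf == paste0("t", i)],
                   cf >= 0.4 && nf < 0.5)
    }
  }
})
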