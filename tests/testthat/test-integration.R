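test_that("expression-on-copy-number regression matches closed-form OLS", {
  # exact linear coupling: slope 2, intercept 1
  cn <- matrix(c(1.5, 2, 2.5, 3, 3.5), 1, 5,
               dimnames = list("g1", paste0("S", 1:5)))
  expr <- 2 * cn + 1
  rownames(expr) <- "g1"
  tab <- correlate_ge_cnv(expr, cn)
  expect_equal(tab$beta, 2, tolerance = 1e-12)
  expect_lt(tab$p_value, 1e-12)

  # 5-point fixture against hand OLS
  x <- c(1.8, 2.0, 2.2, 3.1, 3.9)
  y <- c(5.1, 5.0, 5.6, 6.8, 7.2)
  cn2 <- matrix(x, 1, 5, dimnames = list("g", paste0("S", 1:5)))
  e2 <- matrix(y, 1, 5, dimnames = list("g", paste0("S", 1:5)))
  tab2 <- correlate_ge_cnv(e2, cn2)
  ls <- stats::summary.lm(stats::lm(y ~ x))$coefficients
  expect_equal(tab2$beta, unname(ls["x", "Estimate"]), tolerance = 1e-12)
  expect_equal(tab2$p_value, unname(ls["x", "Pr(>|t|)"]), tolerance = 1e-12)

  # zero-variance copy number flagged inestimable
  cn3 <- matrix(2, 1, 5, dimnames = dimnames(cn2))
  tab3 <- correlate_ge_cnv(e2, cn3)
  expect_false(tab3$converged)
  expect_true(is.na(tab3$beta))
})

test_that("null expression/copy-number pairs give slopes within 3 SE", {
  set.seed(8)
  n <- 200
  cn <- matrix(rnorm(n, 2, 0.3), 1, n,
               dimnames = list("g", paste0("S", 1:n)))
  e <- matrix(rnorm(n, 5, 1), 1, n, dimnames = dimnames(cn))
  tab <- correlate_ge_cnv(e, cn)
  expect_lt(abs(tab$beta), 3 * tab$se)
})

assoc_table <- function(genes, p, direction) {
  n <- length(genes)
  tab <- data.frame(gene = genes, beta = direction * 1,
                    hazard_ratio = rep(NA_real_, n),
                    se = rep(0.1, n), p_value = p, direction = direction,
                    converged = rep(TRUE, n), n_used = rep(10L, n),
                    n_events = rep(8L, n), kind = rep("GE~survival", n),
                    significant = rep(NA, n),
                    stringsAsFactors = FALSE)
  class(tab) <- c("association_table", "data.frame")
  tab
}

test_that("replicated overlap requires significance and matching direction", {
  a <- assoc_table(c("g1", "g2", "g3", "g4"),
                   p = c(0.01, 0.02, 0.03, 0.5),
                   direction = c(1, 1, -1, 1))
  b <- assoc_table(c("g1", "g2", "g3", "g4"),
                   p = c(0.02, 0.01, 0.04, 0.01),
                   direction = c(1, -1, -1, 1))
  expect_setequal(replicated_overlap(a, b, 0.05), c("g1", "g3"))
  # disjoint universes -> empty
  b2 <- assoc_table(c("h1", "h2"), c(0.01, 0.01), c(1, 1))
  expect_length(replicated_overlap(a, b2, 0.05), 0)
})

test_that("overlap FDR follows the expected-chance-overlap construction", {
  expect_equal(overlap_fdr(1000, c(0, 0.05), 2, 10), 0)
  expect_equal(overlap_fdr(1000, c(0.5, 0.5), 2, 10), 1)  # capped
  # the replicated-overlap worked example: ~17%
  expect_equal(overlap_fdr(9650, c(0.05, 0.05), 2, 71),
               9650 * 0.0025 / 2 / 71)
  expect_equal(round(overlap_fdr(9650, c(0.05, 0.05), 2, 71), 2), 0.17)
  expect_error(overlap_fdr(100, 0.05, 2, 0), ">= 1")
})

test_that("triple signature admits only direction-coherent genes", {
  ge_s <- assoc_table(c("up", "down", "mix", "ns"),
                      p = c(0.01, 0.01, 0.01, 0.5),
                      direction = c(1, -1, 1, 1))
  cnv_s <- assoc_table(c("up", "down", "mix", "ns"),
                       p = c(0.01, 0.01, 0.01, 0.01),
                       direction = c(1, -1, -1, 1))
  ge_cnv <- assoc_table(c("up", "down", "mix", "ns"),
                        p = c(0.01, 0.01, 0.01, 0.01),
                        direction = c(1, 1, 1, 1))
  sig <- triple_signature(ge_s, cnv_s, ge_cnv, 0.05)
  expect_setequal(sig$gene, c("up", "down", "mix"))
  expect_equal(sig$class[sig$gene == "up"], "gain_up")
  expect_equal(sig$class[sig$gene == "down"], "deletion_down")
  expect_false(sig$coherent[sig$gene == "mix"])
  # empty input -> empty signature
  empty <- assoc_table(character(0), numeric(0), numeric(0))
  expect_equal(nrow(triple_signature(empty, cnv_s, ge_cnv, 0.05)), 0)
})

test_that("overlap and signature are monotone in alpha", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:150)
  mk <- function() assoc_table(genes, runif(150),
                               sample(c(-1, 1), 150, replace = TRUE))
  a <- mk(); b <- mk(); c3 <- mk()
  c3$direction <- abs(c3$direction)
  for (al in list(c(0.01, 0.05), c(0.05, 0.2))) {
    expect_true(all(replicated_overlap(a, b, al[1]) %in%
                      replicated_overlap(a, b, al[2])))
    s1 <- triple_signature(a, b, c3, al[1])$gene
    s2 <- triple_signature(a, b, c3, al[2])$gene
    expect_true(all(s1 %in% s2))
  }
})

test_that("planted risk genes reach the signature; null coupling does not", {
  cfg <- synthetic_config(seed = 17L)
  co <- generate_cohort(cfg)
  ge_s <- genewise_screen(co$expression, co$clinical, kind = "GE~survival")
  cnv_s <- genewise_screen(co$cnv_categorical, co$clinical,
                           kind = "CNV~survival")
  ge_cnv <- correlate_ge_cnv(co$expression, co$cnv_continuous)
  sig <- triple_signature(ge_s, cnv_s, ge_cnv, 0.05)
  expect_true(all(cfg$planted_genes$symbol %in% sig$gene[sig$coherent]))
  expect_true(all(sig$class[sig$gene %in% cfg$planted_genes$symbol] ==
                    "gain_up"))

  # a gene coupled to copy number but with zero hazard effect is excluded
  planted0 <- data.frame(
    symbol = c("NULLG", "RISK1"),
    cnv_gain_prevalence = 0.4, ge_cnv_slope = 1.0,
    log_hazard_per_unit_expression = c(0, 0.7))
  co0 <- generate_cohort(synthetic_config(planted_genes = planted0,
                                          n_genes = 50, seed = 23L))
  sig0 <- triple_signature(
    genewise_screen(co0$expression, co0$clinical),
    genewise_screen(co0$cnv_categorical, co0$clinical, kind = "CNV~survival"),
    correlate_ge_cnv(co0$expression, co0$cnv_continuous), 0.05)
  expect_false("NULLG" %in% sig0$gene[sig0$coherent])
})

test_that("fold change versus normal is the geometric-mean ratio", {
  genes <- paste0("g", 1:3)
  normal <- matrix(5, 3, 4, dimnames = list(genes, paste0("N", 1:4)))
  tumor <- normal[, 1:4] + log2(4)  # 4x on the linear scale
  colnames(tumor) <- paste0("T", 1:4)
  fc <- fold_change_vs_normal(tumor, normal)
  expect_equal(fc$fold_change, rep(4, 3))
  expect_error(fold_change_vs_normal(tumor[, 1, drop = FALSE], normal),
               "at least 2")
})

test_that("Wilcoxon p matches the exhaustive permutation oracle (4 vs 4)", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4, 1)
    tumor <- matrix(x, 1, 4, dimnames = list("g", paste0("T", 1:4)))
    normal <- matrix(y, 1, 4, dimnames = list("g", paste0("N", 1:4)))
    fc <- fold_change_vs_normal(tumor, normal)
    expect_equal(fc$p_value, wilcoxon_perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical distributions give unit fold change and uniform p", {
  set.seed(14)
  genes <- sprintf("g%03d", 1:300)
  normal <- matrix(rnorm(300 * 10, 5), 300, 10,
                   dimnames = list(genes, paste0("N", 1:10)))
  tumor <- matrix(rnorm(300 * 10, 5), 300, 10,
                  dimnames = list(genes, paste0("T", 1:10)))
  fc <- fold_change_vs_normal(tumor, normal)
  # fold changes are geometric-mean ratios, so the null center is 1 on the
  # log scale (the arithmetic mean of the ratio itself is biased upward)
  expect_equal(mean(log2(fc$fold_change)), 0, tolerance = 0.05)
  # exact Wilcoxon p-values at n = 10 vs 10 are discrete and super-uniform,
  # so test the moments that are stable under discreteness: the null mean of
  # p sits at 0.5 plus a small atom-size bias (< 0.02 here), and the
  # rejection rate at 0.05 cannot exceed the nominal level
  expect_lt(abs(mean(fc$p_value) - 0.5), 0.02 + 3 * sqrt(1 / 12 / 300))
  expect_lt(mean(fc$p_value <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  # BH adjustment: adjusted >= raw, monotone in raw-p rank order
  o <- order(fc$p_value)
  expect_true(all(fc$p_adjusted >= fc$p_value))
  expect_true(all(diff(fc$p_adjusted[o]) >= -1e-15))
})

test_that("risk prevalence counts categories and ignores sample order", {
  m <- matrix(c(rep(1L, 9), 0L), 1, 10,
              dimnames = list("MYC", paste0("P", 1:10)))
  expect_equal(risk_prevalence(m, "MYC", 1), 0.9)
  expect_equal(risk_prevalence(m, "MYC", 1, include_normal = TRUE), 1.0)
  m_all <- matrix(1L, 1, 6, dimnames = list("MYC", paste0("P", 1:6)))
  expect_equal(risk_prevalence(m_all, "MYC", 1), 1.0)
  set.seed(3)
  perm <- m[, sample(10), drop = FALSE]
  expect_equal(risk_prevalence(perm, "MYC", 1), 0.9)
  expect_error(risk_prevalence(m, "RAD21", 1), "absent")
})

test_that("the funnel enforces flags, prevalence threshold and p ranking", {
  sig <- data.frame(gene = c("A", "B", "C", "D"),
                    class = "gain_up", coherent = TRUE,
                    ge_surv_beta = 1, ge_surv_p = 0.01,
                    cnv_surv_beta = 1,
                    cnv_surv_p = c(0.04, 0.001, 0.01, 0.002),
                    ge_cnv_slope = 1, ge_cnv_p = 0.01,
                    stringsAsFactors = FALSE)
  class(sig) <- c("signature_table", "data.frame")
  flags <- data.frame(gene = c("A", "B", "C", "D"),
                      targetable_network = TRUE,
                      inhibitor_available = c(TRUE, TRUE, FALSE, TRUE),
                      model_available = TRUE)
  prev <- c(A = 0.95, B = 0.92, C = 0.99, D = 0.89)
  out <- apply_funnel(sig, flags, prev, prevalence_threshold = 0.9)
  expect_equal(out$gene, c("B", "A"))  # C fails a flag, D fails prevalence
})
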