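# PWM scoring, calibration quantiles, breaker enumeration and the
# kinase-substrate network.

uniform_pwm <- function(kinase = "U1") {
  m <- matrix(0.05, 15, 20, dimnames = list(as.character(-7:7), AA_ALPHABET))
  structure(list(kinase = kinase, matrix = m), class = "ptmvar_pwm")
}

sharp_pwm <- function(kinase = "S1", p_pref = 0.8) {
  m <- matrix(0.05, 15, 20, dimnames = list(as.character(-7:7), AA_ALPHABET))
  # three informative columns: -3 R, +1 L, +4 E; centre S
  for (col in list(c("-3", "R"), c("1", "L"), c("4", "E"))) {
    v <- rep((1 - p_pref) / 19, 20); names(v) <- AA_ALPHABET
    v[col[2]] <- p_pref
    m[col[1], ] <- v
  }
  v <- rep(0.01 / 19, 20); names(v) <- AA_ALPHABET; v["S"] <- 0.99
  m["0", ] <- v / sum(v)
  structure(list(kinase = kinase, matrix = m), class = "ptmvar_pwm")
}

test_that("a uniform PWM scores every window 0.05^15 (pseudocounted)", {
  pw <- uniform_pwm()
  w <- strrep("A", 15)
  pc <- (0.05 + 1e-3) / (1 + 20e-3)
  expect_equal(score_site(pw, w), pc^15, tolerance = 1e-12)
  expect_equal(score_site(pw, paste(rep(c("S", "K", "R"), 5), collapse = "")),
               pc^15, tolerance = 1e-12)
})

test_that("the consensus window maximizes the score of a sharp PWM", {
  pw <- sharp_pwm()
  cons <- paste(pwm_consensus(pw), collapse = "")
  sc_cons <- score_site(pw, cons)
  set.seed(61)
  for (i in 1:50) {
    w <- paste(sample(AA_ALPHABET, 15, replace = TRUE), collapse = "")
    expect_lte(score_site(pw, w), sc_cons)
  }
})

test_that("scores equal the hand-computed product of column probabilities", {
  pw <- sharp_pwm()
  pm <- pwm_probs(pw)
  w <- "AAAARAAASLAAEAA"  # R at -3, centre S, L at +1, E at +4
  chars <- strsplit(w, "")[[1]]
  manual <- prod(vapply(1:15, function(k) pm[k, chars[k]], 0))
  expect_equal(score_site(pw, w), manual, tolerance = 1e-12)
  # replacing a residue with a higher-probability one never lowers the score
  w_worse <- w; substr(w_worse, 5, 5) <- "A"   # R -> A at the informative column
  expect_lt(score_site(pw, w_worse), score_site(pw, w))
})

test_that("terminal windows are padded and score the column mean", {
  pw <- uniform_pwm()
  proteome <- c(P = strrep("A", 20))
  w <- flank_windows(proteome, "P", 3L)
  expect_equal(nchar(w), 15L)
  expect_equal(substr(w, 1, 5), "XXXXX")
  expect_true(is.finite(score_site(pw, w)))
  expect_error(score_site(pw, strrep("Z", 15)), "non-amino-acid")
})

test_that("calibration uses type-7 quantiles of the control scores", {
  pw <- sharp_pwm()
  set.seed(62)
  pos <- vapply(1:20, function(i)
    paste(sample(AA_ALPHABET, 15, TRUE), collapse = ""), "")
  neg <- vapply(1:150, function(i)
    paste(sample(AA_ALPHABET, 15, TRUE), collapse = ""), "")
  cal <- calibrate_pwm(pw, pos, neg)
  expect_equal(cal$thresholds[["pos10"]],
               unname(quantile(score_windows(pw, pos), 0.10, type = 7)))
  expect_equal(cal$thresholds[["neg90"]],
               unname(quantile(score_windows(pw, neg), 0.90, type = 7)))
  expect_equal(cal$thresholds[["cutoff"]],
               max(cal$thresholds[["pos10"]], cal$thresholds[["neg90"]]))
  # identical positives: pos10 equals the common score
  same <- rep(pos[1], 12)
  cal2 <- calibrate_pwm(pw, same, neg)
  expect_equal(cal2$thresholds[["pos10"]], score_site(pw, pos[1]))
  expect_error(calibrate_pwm(pw, pos[1:5], neg), "positive controls")
  expect_error(calibrate_pwm(pw, pos, neg[0]), "negative controls")
})

test_that("breaker enumeration flags informative columns and only those", {
  pw_u <- uniform_pwm()
  bound_u <- data.frame(protein = "P1", position = 20L,
                        window = strrep("A", 15), stringsAsFactors = FALSE)
  expect_null(find_breakers(pw_u, bound_u))

  pw <- sharp_pwm(p_pref = 0.8)
  cons <- paste(pwm_consensus(pw), collapse = "")
  bound <- data.frame(protein = "P1", position = 20L, window = cons,
                      stringsAsFactors = FALSE)
  br <- find_breakers(pw, bound)
  # informative offsets -3, +1, +4: fold = p(pref)/p(min) far above 4
  expect_setequal(br$offset, c(-3L, 1L, 4L))
  pm <- pwm_probs(pw)
  expect_equal(br$fold_change[br$offset == -3L],
               pm["-3", "R"] / min(pm["-3", setdiff(AA_ALPHABET, "R")]),
               tolerance = 1e-12)
  # fold-change symmetry: wt->mut times mut->wt is 1
  f <- pm["-3", "R"] / pm["-3", "A"]
  expect_equal(f * (pm["-3", "A"] / pm["-3", "R"]), 1, tolerance = 1e-12)
})

test_that("a fold change of exactly 4 is a breaker (boundary inclusive)", {
  m <- matrix(0.05, 15, 20, dimnames = list(as.character(-7:7), AA_ALPHABET))
  # construct a column where p(R)/p(min) lands exactly on 4 after pseudocount
  pc <- 1e-3
  p_min_raw <- 0.02
  p_r_raw <- 4 * (p_min_raw + pc) - pc  # so (p_r + pc)/(p_min + pc) = 4
  v <- rep((1 - p_r_raw - p_min_raw) / 18, 20); names(v) <- AA_ALPHABET
  v["R"] <- p_r_raw; v["G"] <- p_min_raw
  m["-2", ] <- v
  pw <- structure(list(kinase = "B1", matrix = m), class = "ptmvar_pwm")
  w <- strrep("A", 15); substr(w, 6, 6) <- "R"
  br <- find_breakers(pw, data.frame(protein = "P1", position = 30L,
                                     window = w, stringsAsFactors = FALSE))
  # pwm_probs renormalizes, preserving the within-column ratio
  expect_true(!is.null(br) && any(br$offset == -2L))
  expect_equal(br$fold_change[br$offset == -2L], 4, tolerance = 1e-9)
})

test_that("kinase-level Fisher uses the exact hypergeometric and BH", {
  # 2x2 [[8,2],[20,80]]: sample OR 16, one-sided hypergeometric tail
  tb <- matrix(c(8, 2, 20, 80), 2, byrow = TRUE)
  p_oracle <- sum(dhyper(8:10, 28, 82, 10))
  expect_equal(fisher.test(tb, alternative = "greater")$p.value, p_oracle,
               tolerance = 1e-12)
  expect_equal((8 * 80) / (2 * 20), 16)
})

test_that("network degrees and the disease-gene degree test behave at the edges", {
  empty <- build_kinase_network(NULL)
  expect_true(is.na(empty$test$p_value))
  bound <- data.frame(kinase = "K1",
                      protein = c("A", "B", "C"), position = c(10L, 20L, 30L),
                      stringsAsFactors = FALSE)
  net1 <- build_kinase_network(bound, disease_genes = "A")
  expect_true(all(net1$degrees$degree == 1L))
  expect_equal(net1$test$p_value, 1)
  # planted degree shift is detected
  set.seed(63)
  kin <- sprintf("K%02d", 1:8)
  subs <- sprintf("G%03d", 1:60)
  dis <- subs[1:15]
  rows <- list()
  for (g in subs) {
    k <- sample(kin, if (g %in% dis) 6L else 2L)
    rows[[g]] <- data.frame(kinase = k, protein = g, position = 10L,
                            stringsAsFactors = FALSE)
  }
  net2 <- build_kinase_network(do.call(rbind, rows), dis)
  expect_lt(net2$test$p_value, 0.001)
})

test_that("planted consensus sites are recovered as bound with breaker flags", {
  ch <- generate_cohort(simulation_config(n_proteins = 150, seed = 64L))
  kin <- names(ch$pwms)[1]
  ch <- plant_motif_breakers(ch, kin, 20L)
  sc <- scan_kinase_motifs(ch, seed = 65L)
  planted <- ch$truth$planted_motifs
  bkey <- paste(sc$bound$protein[sc$bound$kinase == kin],
                sc$bound$position[sc$bound$kinase == kin])
  hit_bound <- mean(paste(planted$protein, planted$position) %in% bkey)
  expect_gte(hit_bound, 0.95)
  # informative-column residues of planted sites are flagged as breakers
  inf_off <- ch$pwms[[kin]]$informative
  brk <- sc$breakers[sc$breakers$kinase == kin, ]
  bkkey <- paste(brk$protein, brk$position)
  flagged <- vapply(seq_len(nrow(planted)), function(j) {
    need <- paste(planted$protein[j], planted$position[j] + inf_off)
    mean(need %in% bkkey)
  }, 0)
  expect_gte(mean(flagged), 0.95)
})
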