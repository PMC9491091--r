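# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Brute-force TFCE: a fresh flood-fill labelling at every threshold.
brute_tfce <- function(stat, mask, E = 0.5, H = 2, dh, conn = 26) {
  d <- dim(stat)
  out <- array(0, dim = d)
  s <- stat
  s[!mask] <- 0
  mx <- max(c(0, s))
  nst <- floor(mx / dh + 1e-12)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (conn == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  for (k in seq_len(nst)) {
    h <- k * dh
    supra <- s >= h
    lab <- array(0L, dim = d)
    cur <- 0L
    for (i in which(supra)) {
      if (lab[i] > 0) next
      cur <- cur + 1L
      queue <- i
      lab[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        z <- (v - 1) %/% (d[1] * d[2]); r <- (v - 1) %% (d[1] * d[2])
        y <- r %/% d[1]; x <- r %% d[1]
        for (j in seq_len(nrow(offs))) {
          xx <- x + offs$dx[j]; yy <- y + offs$dy[j]; zz <- z + offs$dz[j]
          if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
              zz < 0 || zz >= d[3]) next
          w <- 1 + xx + d[1] * (yy + d[2] * zz)
          if (supra[w] && lab[w] == 0) { lab[w] <- cur; queue <- c(queue, w) }
        }
      }
    }
    sizes <- tabulate(lab)
    idx <- which(supra)
    out[idx] <- out[idx] + sizes[lab[idx]]^E * h^H * dh
  }
  out
}

# OLS slope/intercept by explicit normal equations.
normal_eq_fit <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Frame average of an analytic curve by adaptive quadrature.
quadrature_frame_means <- function(f, schedule) {
  t0 <- schedule$start / 60
  t1 <- (schedule$start + schedule$duration) / 60
  vapply(seq_along(t0), function(i)
    stats::integrate(f, t0[i], t1[i], rel.tol = 1e-10)$value /
      (t1[i] - t0[i]), numeric(1))
}

# A small all-role label dictionary matching make_toy_atlas conventions.
toy_dictionary <- function() {
  data.frame(id = 1:5,
             name = c("cerebellar_gray", "cortical_gray", "white_matter",
                      "subcortical", "choroid_plexus"),
             role = c("reference_region", "gray_matter_mask",
                      "white_matter_mask", "subcortical_mask",
                      "choroid_plexus"),
             stringsAsFactors = FALSE)
}

# A uniform label DVR vector for the toy atlas with one choroid value.
toy_label_dvr <- function(cp = 1) {
  c(cerebellar_gray = 1, cortical_gray = 1, white_matter = 1,
    subcortical = 1, choroid_plexus = cp)
}

# 28-row cohort manifest reproducing the recruitment/QC structure:
# 3 movement exclusions and 6 technical exclusions leave 19 analyzable.
make_qc_manifest <- function() {
  groups <- c(rep("CH", 10), rep("DEMENTIA", 7), rep("DSD", 6),
              rep("DELIRIUM", 5))
  n <- length(groups)
  df <- data.frame(subject_id = sprintf("sub-%02d", 1:n), group = groups,
                   stringsAsFactors = FALSE)
  for (a in ASSESSMENTS) df[[a]] <- 0
  df$movement_artifact <- FALSE
  df$technical_issue <- FALSE
  # 9 exclusions in all (3 CH, 3 dementia, 2 DSD, 1 delirium): 3 movement,
  # 6 technical; leaves CH 7, dementia 4, DSD 4, delirium 4
  df$movement_artifact[c(1, 11, 18)] <- TRUE
  df$technical_issue[c(2, 3, 12, 13, 19, 24)] <- TRUE
  df
}
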