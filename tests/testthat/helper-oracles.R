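# Rejection-sampling oracles for the conditional expectations behind RB1
# and RB2.  Everything here works from raw normal draws and the selection
# inequalities; none of the package's closed forms are reused.

# E[Y13 | Z1 ~ z, Y12 ~ y12, Q] for a 3:2:1 design: draw the unconstrained
# triple (Y11, Y12, Y13), keep draws whose Z1 and Y12 fall in narrow
# windows, then impose the selection inequalities against the fixed
# observed competitor values y31 (stage-1 mean of the dropped arm) and
# x22 (runner-up stage-2 cumulative MLE).
rb1_oracle_full <- function(z, y12, y31, x22, n, v2, centre,
                            draws = 2e7, win_z = 1.0, win_y = 0.05,
                            chunk = 2e6) {
  sd1 <- sqrt(v2 / n[1]); sd2 <- sqrt(v2 / n[2]); sd3 <- sqrt(v2 / n[3])
  keep <- numeric(0)
  done <- 0
  while (done < draws) {
    m <- min(chunk, draws - done); done <- done + m
    a <- rnorm(m, centre, sd1)
    b <- rnorm(m, centre, sd2)
    c_ <- rnorm(m, centre, sd3)
    zz <- n[1] * a + n[2] * b + n[3] * c_
    sel <- abs(zz - z) < win_z & abs(b - y12) < win_y
    a <- a[sel]; b <- b[sel]; c_ <- c_[sel]
    q <- a >= y31 & (n[1] * a + n[2] * b) / (n[1] + n[2]) >= x22
    keep <- c(keep, c_[q])
  }
  list(mean = mean(keep), se = sd(keep) / sqrt(length(keep)),
       max = max(keep), n = length(keep))
}

# E[Y13 | Z1 ~ z, Qtilde] (stage-two rule only) for RB2.
rb2_oracle_full <- function(z, x22, n, v2, centre, draws = 4e6,
                            win_z = 1.0, chunk = 2e6) {
  sd1 <- sqrt(v2 / n[1]); sd2 <- sqrt(v2 / n[2]); sd3 <- sqrt(v2 / n[3])
  keep <- numeric(0)
  done <- 0
  while (done < draws) {
    m <- min(chunk, draws - done); done <- done + m
    a <- rnorm(m, centre, sd1)
    b <- rnorm(m, centre, sd2)
    c_ <- rnorm(m, centre, sd3)
    zz <- n[1] * a + n[2] * b + n[3] * c_
    sel <- abs(zz - z) < win_z &
      (n[1] * a + n[2] * b) / (n[1] + n[2]) >= x22
    keep <- c(keep, c_[sel])
  }
  list(mean = mean(keep), se = sd(keep) / sqrt(length(keep)),
       n = length(keep))
}

# Cheaper oracle for parameter sweeps.  Y12 is independent of (Y11, Y13),
# so conditioning on Y12 = y12 exactly and windowing the remainder
# s = n1*Y11 + n3*Y13 of Z1 is equivalent to windowing (Z1, Y12) jointly.
rb1_oracle_pair <- function(z, y12, y31, x22, n, v2, centre,
                            draws = 4e6, win_s = 0.5) {
  sd1 <- sqrt(v2 / n[1]); sd3 <- sqrt(v2 / n[3])
  s_target <- z - n[2] * y12
  a <- rnorm(draws, centre, sd1)
  c_ <- rnorm(draws, centre, sd3)
  sel <- abs(n[1] * a + n[3] * c_ - s_target) < win_s
  a <- a[sel]; c_ <- c_[sel]
  q <- a >= y31 & (n[1] * a + n[2] * y12) / (n[1] + n[2]) >= x22
  keep <- c_[q]
  list(mean = mean(keep), se = sd(keep) / sqrt(length(keep)),
       n = length(keep))
}

# build a 3:2:1 trial outcome with prescribed selected-arm stage means and
# competitor statistics (y31 = dropped arm stage-1 mean, x22 = runner-up
# stage-2 cumulative MLE, split as y21 + y22)
make_321_outcome <- function(y1, y21, y22, y31, design, means = NULL) {
  Y <- matrix(c(y1[1], y21, y31,
                y1[2], y22, NA,
                y1[3], NA, NA), nrow = 3)
  rank_and_select(Y, design, means = means)
}
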