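# shared fixtures and independent oracles, built in code at test time

quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_group = 2, epochs_per_subject = 3, seed = 1L),
    list(...))
  do.call(synth_config, args)
}

# an ms_peaks collection from an arbitrary map matrix (rows = maps)
make_peaks <- function(maps, gfp = rep(1, nrow(maps)), sfreq = 200) {
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  structure(list(maps = maps, gfp = gfp,
                 epoch = rep(1L, nrow(maps)),
                 sample = seq_len(nrow(maps)), sfreq = sfreq),
            class = "ms_peaks")
}

# exhaustive-assignment clustering oracle: max GEV over all 2^n labelings
brute_force_gev <- function(pk, k = 2) {
  n <- nrow(pk$maps)
  stopifnot(n <= 12)
  w <- pk$gfp^2
  best <- -Inf
  for (m in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(m))[1:n] + 1L
    if (length(unique(lab)) < k) next
    tmpl <- t(sapply(1:k, function(ci) {
      M <- pk$maps[lab == ci, , drop = FALSE]
      S <- crossprod(M * sqrt(w[lab == ci]))
      v <- eigen(S, symmetric = TRUE)$vectors[, 1]
      v / sqrt(sum(v^2))
    }))
    g <- compute_gev(pk, tmpl, lab)
    if (g > best) best <- g
  }
  best
}

# run-length encoding by explicit scan
rle_oracle <- function(lab) {
  runs <- list()
  start <- 1
  for (i in seq_along(lab)[-1]) {
    if (lab[i] != lab[i - 1]) {
      runs[[length(runs) + 1]] <- c(start = start, end = i - 1)
      start <- i
    }
  }
  runs[[length(runs) + 1]] <- c(start = start, end = length(lab))
  tibble::tibble(
    class = vapply(runs, function(r) lab[r["start"]], character(1)),
    start = vapply(runs, function(r) unname(r["start"]), numeric(1)),
    n_samples = vapply(runs, function(r) unname(r["end"] - r["start"] + 1),
                       numeric(1))
  )
}

# textbook split-plot sums-of-squares decomposition (two groups, k classes)
splitplot_oracle <- function(df) {
  # df: subject, group, class, y; balanced
  gm <- mean(df$y)
  k <- length(unique(df$class))
  n_sub <- length(unique(df$subject))
  sub_means <- tapply(df$y, df$subject, mean)
  sub_group <- tapply(as.character(df$group), df$subject, `[`, 1)
  grp_means <- tapply(df$y, df$group, mean)
  cls_means <- tapply(df$y, df$class, mean)
  cell_means <- tapply(df$y, list(df$group, df$class), mean)
  n_per_grp <- table(sub_group)

  ss_group <- k * sum(n_per_grp * (grp_means[names(n_per_grp)] - gm)^2)
  ss_subj <- k * sum((sub_means - grp_means[sub_group])^2)
  ss_class <- n_sub * sum((cls_means - gm)^2)
  ss_int <- sum(outer(n_per_grp[rownames(cell_means)], rep(1, k)) *
                  (cell_means - outer(grp_means[rownames(cell_means)], rep(1, k)) -
                     outer(rep(1, nrow(cell_means)), cls_means) + gm)^2)
  resid <- df$y - sub_means[as.character(df$subject)] -
    cell_means[cbind(as.character(df$group), as.character(df$class))] +
    grp_means[as.character(df$group)]
  ss_err <- sum(resid^2)

  df_subj <- n_sub - 2
  df_err <- (k - 1) * (n_sub - 2)
  list(
    F_group = (ss_group / 1) / (ss_subj / df_subj),
    F_class = (ss_class / (k - 1)) / (ss_err / df_err),
    F_int = (ss_int / (k - 1)) / (ss_err / df_err),
    df_subj = df_subj, df_err = df_err
  )
}

# mean of a normal truncated from below at `lower`
truncnorm_mean_oracle <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}
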