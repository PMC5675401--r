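# Clone-based bisulfite methylation calling, per-context aggregation, and
# replicate-level genotype comparisons.
#
# The statistical unit for genotype contrasts is the biological replicate
# (plant); technical clones are pooled within a replicate. Percent
# methylation in a context = 100 * methylated calls / informative calls,
# pooling all clones; ambiguous bases (neither C nor T at a site, in
# read-strand orientation) are excluded from both numerator and denominator.

#' Call methylation states from a clone set
#'
#' For every (site, clone) pair: C at the site (read-strand orientation)
#' means the cytosine was methylated and survived bisulfite conversion, T
#' means it was unmethylated and converted, anything else is ambiguous.
#'
#' @param clone_set A `CloneSet` (gap-free, amplicon-length clones).
#' @param sites data.frame from [enumerate_sites()], restricted to the
#'   amplicon and to the clone set's strand.
#' @param ambiguity_warn_rate Clone-level ambiguous-call fraction above
#'   which a message flags the clone (the clone is kept).
#' @return data.frame with one row per (site, clone): `array_pos`,
#'   `tss_pos`, `strand`, `context`, `clone_index`, `state`.
#' @export
call_methylation <- function(clone_set, sites, ambiguity_warn_rate = 0.1) {
  stopifnot(inherits(clone_set, "CloneSet"))
  amp <- clone_set$amplicon
  # Linearize the no-zero TSS coordinates so lengths/offsets are plain
  # differences even when the amplicon straddles the TSS.
  lin <- function(t) ifelse(t > 0L, t, t + 1L)
  amp_len <- lin(amp[2L]) - lin(amp[1L]) + 1L
  if (any(nchar(clone_set$clones) != amp_len)) {
    stop("clone length differs from amplicon length")
  }
  if (any(sites$strand != clone_set$strand)) {
    stop("sites on the wrong strand for this clone set")
  }
  if (any(sites$tss_pos < min(amp) | sites$tss_pos > max(amp))) {
    stop("sites outside the amplicon")
  }
  n_sites <- nrow(sites)
  n_clones <- length(clone_set$clones)
  if (n_sites == 0L) {
    return(data.frame(array_pos = integer(0), tss_pos = integer(0),
                      strand = character(0), context = character(0),
                      clone_index = integer(0), state = character(0),
                      stringsAsFactors = FALSE))
  }
  # Site offset within the read-strand clone string.
  rel <- lin(sites$tss_pos) - lin(amp[1L])
  off <- if (clone_set$strand == "+") rel + 1L else amp_len - rel
  base <- vapply(clone_set$clones,
                 function(cl) substring(cl, off, off),
                 character(n_sites), USE.NAMES = FALSE)
  base <- matrix(base, nrow = n_sites, ncol = n_clones)
  state <- matrix("ambiguous", n_sites, n_clones)
  state[base == "C"] <- "methylated"
  state[base == "T"] <- "unmethylated"

  amb_rate <- colMeans(state == "ambiguous")
  flagged <- which(amb_rate > ambiguity_warn_rate)
  if (length(flagged)) {
    message(sprintf("clone(s) %s of %s have > %.0f%% ambiguous calls",
                    paste(flagged, collapse = ","),
                    clone_set$replicate_id, 100 * ambiguity_warn_rate))
  }
  data.frame(
    array_pos = rep(sites$array_pos, times = n_clones),
    tss_pos = rep(sites$tss_pos, times = n_clones),
    strand = clone_set$strand,
    context = rep(sites$context, times = n_clones),
    clone_index = rep(seq_len(n_clones), each = n_sites),
    state = as.vector(state),
    stringsAsFactors = FALSE
  )
}

#' Summarize methylation calls into a profile
#'
#' Aggregates calls per site, per context (pooled over clones), and per
#' feature subset. Sites with context `UNKNOWN` and ambiguous calls are
#' excluded from all tallies; a context with zero informative calls has
#' percent `NA` (missing, not 0).
#'
#' @param calls data.frame from [call_methylation()].
#' @param feature_subsets Optional data.frame with columns `name`, `start`,
#'   `end` (inclusive TSS-relative) defining sub-region tallies, e.g.
#'   Int2-1 vs Int2-2.
#' @param mask Optional list of length-2 TSS-relative intervals (e.g.
#'   nested-primer footprints); sites inside any are dropped first.
#' @return A `MethylationProfile`: list with `per_site`, `per_context`,
#'   `per_feature`, `n_clones`.
#' @export
summarize_profile <- function(calls, feature_subsets = NULL, mask = NULL) {
  if (!is.null(mask)) {
    for (iv in mask) {
      calls <- calls[!(calls$tss_pos >= iv[1L] & calls$tss_pos <= iv[2L]), ,
                     drop = FALSE]
    }
  }
  n_clones <- if (nrow(calls)) max(calls$clone_index) else 0L
  known <- calls[calls$context %in% CONTEXTS, , drop = FALSE]

  tally <- function(df, by) {
    if (nrow(df) == 0L) {
      out <- df[0L, by, drop = FALSE]
      out$n_meth <- out$n_unmeth <- out$n_ambig <- integer(0)
      return(out)
    }
    counts <- data.frame(n_meth = as.integer(df$state == "methylated"),
                         n_unmeth = as.integer(df$state == "unmethylated"),
                         n_ambig = as.integer(df$state == "ambiguous"))
    aggregate(counts, by = df[, by, drop = FALSE], FUN = sum)
  }

  per_site <- tally(known, c("array_pos", "tss_pos", "strand", "context"))
  if (nrow(per_site)) {
    inf <- per_site$n_meth + per_site$n_unmeth
    per_site$fraction <- ifelse(inf > 0, per_site$n_meth / inf, NA_real_)
    per_site <- per_site[order(per_site$array_pos, per_site$strand), ]
    rownames(per_site) <- NULL
  } else {
    per_site$fraction <- numeric(0)
  }

  ctx_tally <- function(df) {
    out <- data.frame(context = CONTEXTS, meth_calls = 0L,
                      total_informative_calls = 0L, percent = NA_real_,
                      stringsAsFactors = FALSE)
    if (nrow(df)) {
      t1 <- tally(df, "context")
      m <- match(t1$context, out$context)
      out$meth_calls[m] <- t1$n_meth
      out$total_informative_calls[m] <- t1$n_meth + t1$n_unmeth
    }
    out$percent <- ifelse(out$total_informative_calls > 0,
                          100 * out$meth_calls / out$total_informative_calls,
                          NA_real_)
    out
  }
  per_context <- ctx_tally(known)

  per_feature <- NULL
  if (!is.null(feature_subsets) && nrow(feature_subsets)) {
    per_feature <- do.call(rbind, lapply(seq_len(nrow(feature_subsets)),
                                         function(i) {
      f <- feature_subsets[i, ]
      sub <- known[known$tss_pos >= f$start & known$tss_pos <= f$end, ,
                   drop = FALSE]
      cbind(feature = f$name, ctx_tally(sub), stringsAsFactors = FALSE)
    }))
  }

  structure(list(per_site = per_site, per_context = per_context,
                 per_feature = per_feature, n_clones = n_clones,
                 n_calls = nrow(calls)),
            class = "MethylationProfile")
}

#' @export
print.MethylationProfile <- function(x, ...) {
  cat(sprintf("MethylationProfile: %d clones, %d sites\n", x$n_clones,
              nrow(x$per_site)))
  print(x$per_context)
  invisible(x)
}

#' Classical two-sample Student t-test on replicate percents
#'
#' Equal-variance, two-sided, as used for genotype contrasts of per-context
#' methylation percents.
#'
#' @param a,b Numeric vectors of replicate-level percents.
#' @return List with `mean_a`, `se_a`, `n_a`, `mean_b`, `se_b`, `n_b`,
#'   `t_statistic`, `p_value`, `significant`, `complete` (FALSE when either
#'   group has fewer than 2 replicates, in which case no t/P is reported).
#' @export
meth_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  res <- list(mean_a = mean(a), se_a = sd(a) / sqrt(length(a)),
              n_a = length(a),
              mean_b = mean(b), se_b = sd(b) / sqrt(length(b)),
              n_b = length(b),
              t_statistic = NA_real_, p_value = NA_real_,
              significant = NA, complete = FALSE)
  if (length(a) >= 2L && length(b) >= 2L) {
    tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    res$t_statistic <- unname(tt$statistic)
    res$p_value <- tt$p.value
    res$significant <- tt$p.value <= 0.05
    res$complete <- TRUE
  }
  res
}

#' Compare per-context methylation between genotypes
#'
#' Replicate-level percents (one per plant, clones pooled within the plant)
#' are the observations of a classical equal-variance two-sided Student
#' t-test; results are flagged significant at P <= 0.05. With a single
#' replicate in either group (e.g. a single-plant control) the comparison
#' is reported without t/P and flagged incomplete.
#'
#' @param profiles List of entries `list(genotype =, replicate =, profile =)`
#'   where `profile` is a `MethylationProfile`.
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param feature Optional feature-subset name (uses the profiles'
#'   `per_feature` tallies instead of the whole amplicon).
#' @param genotypes Length-2 character vector selecting and ordering the two
#'   genotypes; defaults to the first two seen.
#' @return A one-row data.frame of class `GenotypeComparison`.
#' @export
compare_genotypes <- function(profiles, context, feature = NULL,
                              genotypes = NULL) {
  stopifnot(context %in% CONTEXTS)
  tab <- replicate_context_table(profiles, feature = feature)
  tab <- tab[tab$context == context, , drop = FALSE]
  if (is.null(genotypes)) genotypes <- unique(tab$genotype)[1:2]
  stopifnot(length(genotypes) == 2L)
  a <- tab$percent[tab$genotype == genotypes[1L]]
  b <- tab$percent[tab$genotype == genotypes[2L]]
  tt <- meth_t_test(a, b)
  out <- data.frame(
    context = context, feature = feature %||% NA_character_,
    genotype_a = genotypes[1L], genotype_b = genotypes[2L],
    mean_a = tt$mean_a, se_a = tt$se_a, n_a = tt$n_a,
    mean_b = tt$mean_b, se_b = tt$se_b, n_b = tt$n_b,
    t_statistic = tt$t_statistic, p_value = tt$p_value,
    significant = tt$significant, complete = tt$complete,
    stringsAsFactors = FALSE
  )
  class(out) <- c("GenotypeComparison", class(out))
  out
}

#' Replicate-level per-context percent table
#'
#' @inheritParams compare_genotypes
#' @return data.frame with columns `genotype`, `replicate`, `context`,
#'   `percent`, `calls`.
#' @export
replicate_context_table <- function(profiles, feature = NULL) {
  do.call(rbind, lapply(profiles, function(e) {
    tab <- if (is.null(feature)) {
      e$profile$per_context
    } else {
      pf <- e$profile$per_feature
      if (is.null(pf)) stop("profiles carry no per-feature tallies")
      pf <- pf[pf$feature == feature, , drop = FALSE]
      if (nrow(pf) == 0L) stop("unknown feature subset: ", feature)
      pf
    }
    data.frame(genotype = e$genotype, replicate = e$replicate,
               context = tab$context, percent = tab$percent,
               calls = tab$total_informative_calls,
               stringsAsFactors = FALSE)
  }))
}

#' Per-site methylation table across genotypes
#'
#' One record per (site, genotype) for plotting and export. Default pools
#' clones across replicates within a genotype (the per-site counts are
#' summed before the fraction is taken); `mode = "replicate_mean"` averages
#' the per-replicate fractions instead.
#'
#' @inheritParams compare_genotypes
#' @param mode `"clone_pooled"` (default) or `"replicate_mean"`.
#' @return data.frame sorted by `tss_pos` then `genotype`, with `context`,
#'   `fraction` and `n_informative`.
#' @export
per_site_table <- function(profiles, mode = c("clone_pooled",
                                              "replicate_mean")) {
  mode <- match.arg(mode)
  rows <- do.call(rbind, lapply(profiles, function(e) {
    ps <- e$profile$per_site
    if (nrow(ps) == 0L) return(NULL)
    cbind(genotype = e$genotype, replicate = e$replicate, ps,
          stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(genotype = character(0), tss_pos = integer(0),
                      strand = character(0), context = character(0),
                      fraction = numeric(0), n_informative = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows$n_inf <- rows$n_meth + rows$n_unmeth
  if (mode == "clone_pooled") {
    agg <- aggregate(cbind(n_meth, n_inf) ~
                       genotype + tss_pos + strand + context,
                     data = rows, FUN = sum)
    agg$fraction <- ifelse(agg$n_inf > 0, agg$n_meth / agg$n_inf, NA_real_)
  } else {
    agg <- aggregate(cbind(fraction, n_inf) ~
                       genotype + tss_pos + strand + context,
                     data = rows, FUN = mean)
  }
  agg <- agg[order(agg$tss_pos, agg$genotype), ]
  rownames(agg) <- NULL
  data.frame(genotype = agg$genotype, tss_pos = agg$tss_pos,
             strand = agg$strand, context = agg$context,
             fraction = agg$fraction,
             n_informative = as.integer(round(agg$n_inf)),
             stringsAsFactors = FALSE)
}
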