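#' Cell-type counts and proportions per group
#'
#' Ambiguously annotated nuclei are excluded from the denominators and
#' reported separately by the annotation stage.
#'
#' @param labels Named character label vector (barcodes as names).
#' @param groups Character vector of group assignments aligned to
#'   `labels` (values `"IVF"` / `"SCNT"`).
#' @return data.frame with `group`, `type`, `n`, `proportion`
#'   (proportions sum to 1 within group over non-ambiguous types).
#' @export
type_proportions <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  keep <- labels != "ambiguous"
  labels <- labels[keep]
  groups <- groups[keep]
  if (!length(labels) || any(table(groups) == 0)) {
    stop("a group has no (non-ambiguous) nuclei", call. = FALSE)
  }
  types <- sort(unique(labels))
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    n_g <- sum(groups == g)
    if (n_g == 0) stop("empty group: ", g, call. = FALSE)
    n <- vapply(types, function(tt) sum(labels == tt & groups == g),
                numeric(1))
    data.frame(group = g, type = types, n = n, n_group = n_g,
               proportion = n / n_g, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# pooled two-proportion z-test, two-sided
two_proportion_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Test per-type proportion differences between groups
#'
#' Two-sided pooled two-proportion z-test per type, BH-adjusted across
#' types.  Each nucleus counts as one observation; with nuclei pooled
#' from few placentas per group this is anti-conservative under
#' biological replication (pseudoreplication), which is documented as a
#' caveat of the design rather than corrected.
#'
#' @param prop_table Output of [type_proportions()] with exactly two
#'   groups.
#' @return data.frame per type: counts, proportions per group, `z`, `p`,
#'   `q`, `stars`.
#' @export
compare_type_proportions <- function(prop_table) {
  groups <- sort(unique(prop_table$group))
  if (length(groups) != 2) {
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  g1 <- prop_table[prop_table$group == groups[1], ]
  g2 <- prop_table[prop_table$group == groups[2], ]
  types <- sort(unique(prop_table$type))
  if (g1$n_group[1] < 50 || g2$n_group[1] < 50) {
    warning("fewer than 50 nuclei in a group; z-test may be unreliable")
  }
  res <- do.call(rbind, lapply(types, function(tt) {
    x1 <- sum(g1$n[g1$type == tt])
    x2 <- sum(g2$n[g2$type == tt])
    if (x1 == 0 || x2 == 0) {
      warning("type ", tt, " absent from one group")
    }
    ts <- two_proportion_test(x1, g1$n_group[1], x2, g2$n_group[1])
    data.frame(type = tt,
               n_1 = x1, n_2 = x2,
               prop_1 = x1 / g1$n_group[1], prop_2 = x2 / g2$n_group[1],
               z = ts$z, p = ts$p, stringsAsFactors = FALSE)
  }))
  names(res)[names(res) == "n_1"] <- paste0("n_", groups[1])
  names(res)[names(res) == "n_2"] <- paste0("n_", groups[2])
  names(res)[names(res) == "prop_1"] <- paste0("prop_", groups[1])
  names(res)[names(res) == "prop_2"] <- paste0("prop_", groups[2])
  res$q <- bh_adjust(res$p)
  res$stars <- stars(res$p)
  rownames(res) <- NULL
  res
}

#' Giant-cell shares of the trophoblast compartment
#'
#' Reports, per group, the S-TGC and P-TGC shares of all annotated
#' trophoblast nuclei, their combined TGC share, the S-TGC:P-TGC ratio
#' (`NA` with a warning when a group has no P-TGC), and a two-proportion
#' z-test for the S-TGC share difference between groups.
#'
#' @param subtype_labels Named subtype label vector over trophoblast
#'   nuclei (from [subcluster_trophoblast()], both groups concatenated).
#' @param groups Group assignment aligned to `subtype_labels`.
#' @return List with `shares` (per-group data.frame) and `s_tgc_test`
#'   (z, p for the S-TGC share difference).
#' @export
tgc_subtype_summary <- function(subtype_labels, groups) {
  stopifnot(length(subtype_labels) == length(groups))
  keep <- subtype_labels != "ambiguous"
  labs <- subtype_labels[keep]
  grp <- groups[keep]
  gl <- sort(unique(grp))
  shares <- do.call(rbind, lapply(gl, function(g) {
    n <- sum(grp == g)
    s <- sum(labs == "S-TGC" & grp == g)
    p <- sum(labs == "P-TGC" & grp == g)
    if (p == 0) warning("no P-TGC nuclei in group ", g,
                        "; S-TGC:P-TGC ratio undefined")
    data.frame(group = g, n_trophoblast = n,
               n_stgc = s, n_ptgc = p,
               share_stgc = s / n, share_ptgc = p / n,
               share_tgc = (s + p) / n,
               ratio_s_to_p = if (p > 0) s / p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  test <- if (length(gl) == 2) {
    two_proportion_test(shares$n_stgc[1], shares$n_trophoblast[1],
                        shares$n_stgc[2], shares$n_trophoblast[2])
  } else {
    NULL
  }
  rownames(shares) <- NULL
  list(shares = shares, s_tgc_test = test)
}
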