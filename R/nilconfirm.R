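# QTL confirmation against a near-isogenic line (NIL) panel: classify each
# NIL's trait shift relative to the recurrent background, use the
# introgression geometry to confirm mapped QTL and refine their borders,
# and screen for effects no mapped QTL explains.

#' Validate a NIL definition table
#'
#' NILs carry donor-genotype introgressions on the recurrent background;
#' intervals must be non-degenerate and non-overlapping per NIL and
#' chromosome.
#'
#' @param nils \code{data.frame(nil_id, chromosome, start_cM, end_cM)}, one
#'   row per introgression interval.
#' @return The validated table (invisibly), sorted by nil, chromosome,
#'   start.
#' @export
nil_definitions <- function(nils) {
  req <- c("nil_id", "chromosome", "start_cM", "end_cM")
  if (!all(req %in% names(nils))) {
    stop("NIL table needs columns ", paste(req, collapse = ", "))
  }
  if (any(nils$end_cM <= nils$start_cM)) stop("degenerate introgression interval")
  nils <- nils[order(nils$nil_id, nils$chromosome, nils$start_cM), ]
  for (id in unique(nils$nil_id)) {
    for (ch in unique(nils$chromosome[nils$nil_id == id])) {
      sub <- nils[nils$nil_id == id & nils$chromosome == ch, ]
      if (nrow(sub) > 1 &&
          any(sub$start_cM[-1] < sub$end_cM[-nrow(sub)])) {
        stop("overlapping introgressions for NIL ", id, " on chromosome ", ch)
      }
    }
  }
  rownames(nils) <- NULL
  invisible(nils)
}

#' Classify a NIL's effect against the recurrent background
#'
#' Two-sided Welch test of the NIL's trait values against the background
#' line's; the direction is the sign of the mean difference (NIL minus
#' background) and the level is strong (p < 0.01), weak (0.01 <= p < 0.05)
#' or ns.
#'
#' @param nil_values,background_values Numeric vectors, >= 3 values each.
#' @param nil_id,trait Identifiers carried into the result.
#' @return One-row \code{data.frame}: \code{nil_id, trait, direction}
#'   ("up"/"down"/"none"), \code{level} ("strong"/"weak"/"ns"), \code{p},
#'   \code{mean_diff}.
#' @export
classify_effect <- function(nil_values, background_values,
                            nil_id = NA_character_, trait = NA_character_) {
  if (length(nil_values) < 3 || length(background_values) < 3) {
    stop("need at least 3 values per group")
  }
  w <- welch_test(nil_values, background_values)
  level <- if (w$p < 0.01) "strong" else if (w$p < 0.05) "weak" else "ns"
  direction <- if (level == "ns") "none" else if (w$direction > 0) "up" else "down"
  data.frame(nil_id = nil_id, trait = trait, direction = direction,
             level = level, p = w$p,
             mean_diff = mean(nil_values) - mean(background_values),
             stringsAsFactors = FALSE)
}

# closed-interval helpers on one chromosome ---------------------------------

intersect_interval <- function(a, b) {
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (lo > hi) NULL else c(lo, hi)
}

union_intervals <- function(ints) {
  if (!length(ints)) return(list())
  ints <- ints[order(vapply(ints, `[`, numeric(1), 1))]
  out <- list(ints[[1]])
  for (iv in ints[-1]) {
    last <- out[[length(out)]]
    if (iv[1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], iv[2]))
    } else out[[length(out) + 1]] <- iv
  }
  out
}

subtract_intervals <- function(ints, minus) {
  # closed-interval subtraction; boundary points shared with the subtracted
  # set are kept (zero-measure), matching border-refinement semantics
  for (mv in minus) {
    nxt <- list()
    for (iv in ints) {
      if (mv[2] <= iv[1] || mv[1] >= iv[2]) { nxt[[length(nxt) + 1]] <- iv; next }
      if (mv[1] > iv[1]) nxt[[length(nxt) + 1]] <- c(iv[1], min(mv[1], iv[2]))
      if (mv[2] < iv[2]) nxt[[length(nxt) + 1]] <- c(max(mv[2], iv[1]), iv[2])
    }
    ints <- nxt
  }
  ints
}

#' Confirm a QTL call against a NIL panel
#'
#' A NIL covers the QTL when one of its introgressions intersects the
#' call's [start, end] interval on the same chromosome. Because the
#' introgressions carry the donor (B-type) allele into the recurrent
#' background, the expected NIL effect direction is opposite to the sign of
#' ADD (the A-allele effect): "down" for a positive ADD, "up" for a
#' negative one. Status: \code{not_covered} when no NIL covers the call;
#' \code{confirmed} when at least one covering NIL shifts the trait
#' significantly (weak or strong) in the expected direction — the refined
#' region is then the QTL interval intersected with the union of the
#' confirming introgressions, minus the introgressions of covering NILs
#' with ns effects; \code{opposite_sign} when all covering significant
#' effects contradict the expectation; \code{not_confirmed} when all
#' covering NILs are ns.
#'
#' @param qtl_call One-row QTL call (\code{\link{call_qtl}}).
#' @param qtl_sign Sign of the call's ADD (defaults to
#'   \code{sign(qtl_call$add)}).
#' @param nils Validated NIL table (\code{\link{nil_definitions}} layout).
#' @param effect_calls Rows from \code{\link{classify_effect}} for the
#'   call's trait, one per NIL.
#' @return List of class \code{confirmation_result}: \code{status},
#'   \code{explaining_nils}, \code{refined} (\code{data.frame(start_cM,
#'   end_cM)} segments, zero rows if none), \code{covering_nils}.
#' @export
confirm_qtl <- function(qtl_call, qtl_sign = NULL, nils, effect_calls) {
  nils <- nil_definitions(nils)
  if (is.null(qtl_sign)) qtl_sign <- sign(qtl_call$add)
  expected <- if (qtl_sign > 0) "down" else "up"
  qiv <- c(qtl_call$start_cM, qtl_call$end_cM)
  on_ch <- nils[nils$chromosome == qtl_call$chromosome, , drop = FALSE]
  covering <- on_ch[apply(on_ch[, c("start_cM", "end_cM")], 1, function(iv) {
    !is.null(intersect_interval(qiv, iv))
  }), , drop = FALSE]
  result <- function(status, explaining = character(0), refined = NULL) {
    if (is.null(refined)) {
      refined <- data.frame(start_cM = numeric(0), end_cM = numeric(0))
    }
    structure(list(status = status, explaining_nils = explaining,
                   refined = refined,
                   covering_nils = unique(covering$nil_id)),
              class = "confirmation_result")
  }
  if (nrow(covering) == 0) return(result("not_covered"))
  eff <- effect_calls[match(unique(covering$nil_id), effect_calls$nil_id), ]
  if (any(is.na(eff$nil_id))) stop("missing effect call for a covering NIL")
  sig <- eff$level != "ns"
  agree <- sig & eff$direction == expected
  if (!any(sig)) return(result("not_confirmed"))
  if (!any(agree)) return(result("opposite_sign"))
  conf_ids <- eff$nil_id[agree]
  ns_ids <- eff$nil_id[!sig]
  conf_ints <- lapply(which(covering$nil_id %in% conf_ids), function(i) {
    c(covering$start_cM[i], covering$end_cM[i])
  })
  ns_ints <- lapply(which(covering$nil_id %in% ns_ids), function(i) {
    c(covering$start_cM[i], covering$end_cM[i])
  })
  region <- lapply(union_intervals(conf_ints), intersect_interval, b = qiv)
  region <- Filter(Negate(is.null), region)
  region <- subtract_intervals(region, ns_ints)
  refined <- if (length(region)) {
    data.frame(start_cM = vapply(region, `[`, numeric(1), 1),
               end_cM = vapply(region, `[`, numeric(1), 2))
  } else NULL
  result("confirmed", explaining = conf_ids, refined = refined)
}

#' Screen for NIL effects unexplained by mapped QTL
#'
#' Significant NIL effects whose introgressions intersect no called QTL
#' interval for the same trait point at loci the genome scan missed.
#'
#' @param effect_calls Rows from \code{\link{classify_effect}} (with
#'   \code{nil_id} and \code{trait} filled).
#' @param qtl_calls QTL call table with a \code{trait} column.
#' @param nils Validated NIL table.
#' @return \code{data.frame(nil_id, trait, direction, level)} of unexplained
#'   significant effects (zero rows if none).
#' @export
extra_qtl_screen <- function(effect_calls, qtl_calls, nils) {
  nils <- nil_definitions(nils)
  sig <- effect_calls[effect_calls$level != "ns", , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(nil_id = character(0), trait = character(0),
                      direction = character(0), level = character(0)))
  }
  unexplained <- vapply(seq_len(nrow(sig)), function(i) {
    ints <- nils[nils$nil_id == sig$nil_id[i], , drop = FALSE]
    qs <- qtl_calls[qtl_calls$trait == sig$trait[i], , drop = FALSE]
    if (nrow(qs) == 0) return(TRUE)
    for (j in seq_len(nrow(ints))) {
      hit <- qs$chromosome == ints$chromosome[j] &
        qs$start_cM <= ints$end_cM[j] & qs$end_cM >= ints$start_cM[j]
      if (any(hit)) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- sig[unexplained, c("nil_id", "trait", "direction", "level")]
  rownames(out) <- NULL
  out
}
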