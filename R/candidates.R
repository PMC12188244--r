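# Candidate-gene derivation: select-set members intersected with significant
# DEGs, manual annotation-based additions, and the exclusion rules.

#' Exclusion policy for candidate genes
#'
#' @param drop_early_only drop genes whose only significant call is the
#'   early (control vs T1day) contrast — their expression pattern does not
#'   track the observed phenotype change (default TRUE).
#' @param blacklist gene ids removed outright (e.g. an androgen-conversion
#'   enzyme like srd5a2 whose change reflects the treatment itself).
#' @return object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(drop_early_only = TRUE, blacklist = character()) {
  stop_unless(is.logical(drop_early_only) && length(drop_early_only) == 1,
              "'drop_early_only' must be a flag")
  structure(list(drop_early_only = drop_early_only,
                 blacklist = as.character(blacklist)),
            class = "exclusion_policy")
}

#' Derive the candidate-gene table
#'
#' Candidates are the union of (a) genes belonging to at least one select
#' gene set AND significant in at least one contrast, and (b) manually added
#' genes that are significant in at least one contrast (non-significant
#' manual picks are dropped with a warning). The exclusion rules are then
#' applied to the whole resulting list: early-only genes (significant solely
#' in control vs T1day) when `drop_early_only`, and blacklisted genes — a
#' manual add that is early-only is still excluded.
#'
#' @param select_sets names of the select gene sets.
#' @param library the gene-set library (named list) the select sets live in.
#' @param calls a [combine_calls()] data frame (gene, broad/early/late calls
#'   and, if present, per-contrast log2fc columns used for the FC columns).
#' @param manual_adds character vector of annotation-driven additions.
#' @param policy an [exclusion_policy()].
#' @param themes optional named character vector gene -> free-text theme.
#' @return data frame of class `candidate_table`, sorted by gene id:
#'   gene, source (set_intersection / manual_annotation), gene_sets
#'   (semicolon-joined select sets containing the gene), per-contrast calls
#'   and signed linear fold changes, theme. Excluded genes are attached as
#'   the `excluded` attribute with their reason.
#' @export
derive_candidates <- function(select_sets, library, calls,
                              manual_adds = character(),
                              policy = exclusion_policy(), themes = NULL) {
  stopifnot(inherits(policy, "exclusion_policy"))
  missing_sets <- setdiff(select_sets, names(library))
  stop_unless(length(missing_sets) == 0, "select sets absent from library: %s",
              paste(missing_sets, collapse = ", "))
  sig <- calls$gene[calls$broad != "ns" | calls$early != "ns" |
                      calls$late != "ns"]
  set_members <- unique(unlist(library[select_sets], use.names = FALSE))
  auto <- intersect(set_members, sig)
  manual_ok <- intersect(manual_adds, sig)
  bad_manual <- setdiff(manual_adds, sig)
  if (length(bad_manual))
    warning("manual additions not significant in any contrast, dropped: ",
            paste(bad_manual, collapse = ", "))
  cand <- union(auto, manual_ok)
  if (!length(cand)) {
    out <- data.frame(gene = character(), source = character(),
                      gene_sets = character(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_table", "data.frame")
    attr(out, "excluded") <- data.frame(gene = character(),
                                        reason = character())
    return(out)
  }
  i <- match(cand, calls$gene)
  in_sets <- vapply(cand, function(g) {
    hit <- select_sets[vapply(select_sets, function(s) g %in% library[[s]],
                              logical(1))]
    paste(hit, collapse = ";")
  }, character(1))
  df <- data.frame(
    gene = cand,
    source = ifelse(cand %in% auto, "set_intersection", "manual_annotation"),
    gene_sets = in_sets,
    call_broad = calls$broad[i], call_early = calls$early[i],
    call_late = calls$late[i], stringsAsFactors = FALSE)
  for (cn in c("broad", "early", "late")) {
    lc <- paste0("lfc_", cn)
    if (lc %in% names(calls)) df[[paste0("fc_", cn)]] <- linear_fc(calls[[lc]][i])
  }
  df$theme <- if (is.null(themes)) NA_character_ else
    unname(themes[df$gene])
  reason <- rep(NA_character_, nrow(df))
  if (policy$drop_early_only) {
    early_only <- df$call_early != "ns" & df$call_broad == "ns" &
      df$call_late == "ns"
    reason[early_only] <- "early-only"
  }
  reason[df$gene %in% policy$blacklist] <- "blacklist"
  excluded <- data.frame(gene = df$gene[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  df <- df[is.na(reason), , drop = FALSE]
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("candidate_table", "data.frame")
  attr(df, "excluded") <- excluded
  df
}
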