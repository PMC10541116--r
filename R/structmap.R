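#' Distance-satisfaction thresholds for a cross-linker
#'
#' Defaults encode the DSSO geometry: a mapped link is `satisfied` when its
#' Calpha-Calpha distance is at most 30 Angstrom (linker span plus lysine
#' side chains, inclusive boundary), `moderate` up to 40 Angstrom,
#' `extreme` above 100 Angstrom, and `violated` in between.
#'
#' @param satisfied,moderate,extreme cutoffs in Angstrom; must satisfy
#'   `satisfied <= moderate < extreme`.
#' @return A named list of class `xl_thresholds`.
#' @export
xl_thresholds <- function(satisfied = 30, moderate = 40, extreme = 100) {
  if (!(satisfied <= moderate && moderate < extreme))
    stop("thresholds must satisfy satisfied <= moderate < extreme (got ",
         satisfied, ", ", moderate, ", ", extreme, ")")
  structure(list(satisfied = satisfied, moderate = moderate,
                 extreme = extreme), class = "xl_thresholds")
}

#' Calpha-Calpha Euclidean distance between two residues
#'
#' @param structure an [xl_structure()].
#' @param chain_a,number_a,chain_b,number_b endpoint residues by chain id
#'   and author number.
#' @return Distance in Angstrom, or `NA` with attribute
#'   `"reason" = "missing_in_structure"` when either Calpha is absent.
#' @export
ca_distance <- function(structure, chain_a, number_a, chain_b, number_b) {
  pa <- residue_ca(structure, chain_a, number_a)
  pb <- residue_ca(structure, chain_b, number_b)
  if (anyNA(pa) || anyNA(pb))
    return(structure(NA_real_, reason = "missing_in_structure"))
  sqrt(sum((pa - pb)^2))
}

#' Classify a Calpha-Calpha distance against linker thresholds
#'
#' `satisfied` iff `d <= satisfied`; `moderate` iff
#' `satisfied < d <= moderate`; `extreme` iff `d > extreme`; `violated`
#' otherwise. Vectorised; `NA` distances give `NA`.
#'
#' @param d numeric distances in Angstrom (non-negative).
#' @param thresholds an [xl_thresholds()].
#' @return Character vector of categories.
#' @export
classify_distance <- function(d, thresholds = xl_thresholds()) {
  stopifnot(inherits(thresholds, "xl_thresholds"))
  if (any(!is.na(d) & d < 0)) stop("distances must be non-negative")
  ifelse(is.na(d), NA_character_,
    ifelse(d <= thresholds$satisfied, "satisfied",
      ifelse(d <= thresholds$moderate, "moderate",
        ifelse(d > thresholds$extreme, "extreme", "violated"))))
}

# Resolve one link endpoint (group, residue) on a structure:
# chains for the group come from chain_map; the position is translated by
# the group's residue_transfer (identity when none supplied). Returns a list
# of candidate (chain, author_number, coord) entries, or a failure reason.
resolve_endpoint <- function(structure, group, residue, chain_map, transfers) {
  chains <- chain_map[[group]]
  if (is.null(chains) || length(chains) == 0)
    return(list(reason = "protein_absent"))
  cands <- list()
  reason <- "unaligned"
  for (ch in chains) {
    tr <- transfers[[group]]
    if (is.null(tr)) {
      res <- chain_residues(structure, ch)
      i <- which(res$author_number == residue)
      if (length(i) == 0) next  # reason stays "unaligned"
      if (is.na(res$x[i[1]])) { reason <- "missing_in_structure"; next }
      cands[[length(cands) + 1]] <-
        list(chain = ch, author_number = residue,
             coord = c(res$x[i[1]], res$y[i[1]], res$z[i[1]]))
    } else {
      if (residue < 1 || residue > nrow(tr)) next
      st <- tr$status[residue]
      if (st != "ok") {
        if (st == "missing_in_structure") reason <- "missing_in_structure"
        next
      }
      an <- tr$author_number[residue]
      p <- residue_ca(structure, ch, an)
      if (anyNA(p)) { reason <- "missing_in_structure"; next }
      cands[[length(cands) + 1]] <-
        list(chain = ch, author_number = an, coord = p)
    }
  }
  if (length(cands) == 0) return(list(reason = reason))
  list(candidates = cands)
}

#' Map unique links onto a structure
#'
#' Places each link's endpoints on the structure (via a chain map from
#' groups to chain ids and optional per-group residue transfers), computes
#' the Calpha-Calpha distance and classifies it. When a group maps to
#' several chains (homo-oligomers, or one protein resolved in multiple
#' copies), the chain pair giving the minimal distance is chosen and
#' recorded — the spectroscopy cannot distinguish copies, so the most
#' permissive assignment is reported. Links that cannot be placed carry a
#' reason (`protein_absent`, `unaligned`, `missing_in_structure`) instead of
#' a distance.
#'
#' @param links an `xl_links` data frame.
#' @param structure an [xl_structure()].
#' @param chain_map named list, group id -> character vector of chain ids.
#' @param transfers optional named list, group id -> [residue_transfer()]
#'   (applies to every chain of that group); groups without an entry use
#'   author numbering directly.
#' @param thresholds an [xl_thresholds()].
#' @return A `data.frame` of class `xl_mapped`: the link columns plus
#'   `structure_id`, `chain_a`, `author_a`, `chain_b`, `author_b`,
#'   `distance`, `reason`, `category`.
#' @export
map_links <- function(links, structure, chain_map, transfers = NULL,
                      thresholds = xl_thresholds()) {
  n <- nrow(links)
  chain_a <- chain_b <- rep(NA_character_, n)
  author_a <- author_b <- rep(NA_integer_, n)
  distance <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ea <- resolve_endpoint(structure, links$group_a[i], links$residue_a[i],
                           chain_map, transfers)
    eb <- resolve_endpoint(structure, links$group_b[i], links$residue_b[i],
                           chain_map, transfers)
    if (!is.null(ea$reason) || !is.null(eb$reason)) {
      reasons <- c(ea$reason, eb$reason)
      pick <- c("protein_absent", "unaligned", "missing_in_structure")
      reason[i] <- pick[min(match(reasons, pick))]
      next
    }
    best <- Inf; best_pair <- NULL
    for (ca in ea$candidates) for (cb in eb$candidates) {
      same_residue <- identical(ca$chain, cb$chain) &&
        ca$author_number == cb$author_number
      if (same_residue) next
      d <- sqrt(sum((ca$coord - cb$coord)^2))
      if (d < best) { best <- d; best_pair <- list(ca, cb) }
    }
    if (is.null(best_pair)) { reason[i] <- "missing_in_structure"; next }
    distance[i] <- best
    chain_a[i] <- best_pair[[1]]$chain; author_a[i] <- best_pair[[1]]$author_number
    chain_b[i] <- best_pair[[2]]$chain; author_b[i] <- best_pair[[2]]$author_number
  }
  out <- cbind(as.data.frame(links),
               data.frame(structure_id = rep(structure$id, n),
                          chain_a = chain_a, author_a = author_a,
                          chain_b = chain_b, author_b = author_b,
                          distance = distance, reason = reason,
                          category = classify_distance(distance, thresholds),
                          stringsAsFactors = FALSE))
  class(out) <- unique(c("xl_mapped", class(out)))
  attr(out, "thresholds") <- thresholds
  out
}

#' Satisfaction summary of mapped links
#'
#' Cohort-level fractions over links with a numeric distance (unmappable
#' links are tallied separately and excluded from denominators, matching
#' the convention of reporting fractions "of mapped XLs"), a 5-Angstrom
#' distance histogram split intramolecular vs intermolecular, intra/inter
#' mean distances, and a per-protein breakdown.
#'
#' @param mapped an `xl_mapped` data frame from [map_links()].
#' @param thresholds an [xl_thresholds()]; defaults to those used in
#'   mapping.
#' @return A list of class `xl_satisfaction` with counts, fractions,
#'   `histogram` and `per_protein` data frames.
#' @export
satisfaction_summary <- function(mapped, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- attr(mapped, "thresholds")
  if (is.null(thresholds)) thresholds <- xl_thresholds()
  ok <- !is.na(mapped$distance)
  d <- mapped$distance[ok]
  kind <- mapped$kind[ok]
  n_mapped <- length(d)
  n30 <- sum(d <= thresholds$satisfied)
  n40 <- sum(d <= thresholds$moderate)
  nex <- sum(d > thresholds$extreme)
  frac <- function(x) if (n_mapped == 0) 0 else x / n_mapped
  breaks <- seq(0, max(c(d, thresholds$moderate)) + 5, by = 5)
  bin <- cut(d, breaks, right = TRUE, include.lowest = TRUE)
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  hist$intra_n <- as.integer(table(bin[kind == "intramolecular"]))
  hist$inter_n <- as.integer(table(bin[kind == "intermolecular"]))
  groups <- sort(unique(c(mapped$group_a[ok], mapped$group_b[ok])))
  per_protein <- do.call(rbind, lapply(groups, function(g) {
    sel <- ok & (mapped$group_a == g | mapped$group_b == g)
    dd <- mapped$distance[sel]
    data.frame(group = g, n_mapped = length(dd),
               n_satisfied = sum(dd <= thresholds$satisfied),
               mean_distance = mean(dd), stringsAsFactors = FALSE)
  }))
  if (is.null(per_protein))
    per_protein <- data.frame(group = character(), n_mapped = integer(),
                              n_satisfied = integer(),
                              mean_distance = numeric())
  unmappable <- table(mapped$reason[!ok])
  structure(list(
    n_links = nrow(mapped),
    n_mapped = n_mapped,
    n_unmappable = sum(!ok),
    unmappable_reasons = unmappable,
    n_within_satisfied = n30,
    n_within_moderate = n40,
    n_extreme = nex,
    frac_within_satisfied = frac(n30),
    frac_within_moderate = frac(n40),
    frac_extreme = frac(nex),
    mean_distance_intra = if (any(kind == "intramolecular"))
      mean(d[kind == "intramolecular"]) else NA_real_,
    mean_distance_inter = if (any(kind == "intermolecular"))
      mean(d[kind == "intermolecular"]) else NA_real_,
    thresholds = thresholds,
    histogram = hist,
    per_protein = per_protein
  ), class = "xl_satisfaction")
}

#' @export
print.xl_satisfaction <- function(x, ...) {
  cat("<xl_satisfaction> ", x$n_mapped, " mapped link(s) (",
      x$n_unmappable, " unmappable)\n", sep = "")
  if (x$n_mapped > 0) {
    cat(sprintf("  <= %g A (satisfied): %d (%.1f%%)\n",
                x$thresholds$satisfied, x$n_within_satisfied,
                100 * x$frac_within_satisfied))
    cat(sprintf("  <= %g A:             %d (%.1f%%)\n",
                x$thresholds$moderate, x$n_within_moderate,
                100 * x$frac_within_moderate))
    cat(sprintf("  >  %g A (extreme):  %d\n", x$thresholds$extreme,
                x$n_extreme))
    cat(sprintf("  mean distance intra/inter: %.1f / %.1f A\n",
                x$mean_distance_intra, x$mean_distance_inter))
  }
  invisible(x)
}
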