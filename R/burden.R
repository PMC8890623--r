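# TOP1 domain classification of protein changes, group assignment of samples,
# group pooling, and the random (Ran) / random-high (Ran_H) control sets.

#' Default TOP1 domain map
#'
#' Amino-acid domain partition of human topoisomerase 1 used to group
#' missense mutations: N-Ter 1-214, Core 215-634, Linker 635-711,
#' C-Ter 712-765. Nonsense and frameshift changes are grouped as "Stop"
#' regardless of position.
#'
#' @param gene gene symbol (default \code{"TOP1"}).
#' @return data.frame with columns \code{gene}, \code{domain}, \code{aa_lo},
#'   \code{aa_hi} (1-based inclusive), in ascending order.
#' @export
top1_domain_map <- function(gene = "TOP1") {
  data.frame(gene = gene,
             domain = c("N-Ter", "Core", "Linker", "C-Ter"),
             aa_lo = c(1L, 215L, 635L, 712L),
             aa_hi = c(214L, 634L, 711L, 765L),
             stringsAsFactors = FALSE)
}

check_domain_map <- function(map) {
  stopifnot(all(c("domain", "aa_lo", "aa_hi") %in% names(map)))
  if (any(map$aa_lo > map$aa_hi) || is.unsorted(map$aa_lo) ||
      any(utils::head(map$aa_hi, -1) + 1L != map$aa_lo[-1]))
    stop("domain map must be ascending, non-overlapping and contiguous")
  map
}

#' Parse HGVS-like protein-change strings
#'
#' Understands \code{"p.<ref><pos><alt>"} (missense, or synonymous when
#' ref == alt), \code{"p.<ref><pos>*"} (nonsense) and
#' \code{"p.<ref><pos>fs"} with an optional \code{"*<n>"} tail (frameshift).
#' Anything else — including the empty string of non-coding records — parses
#' to \code{kind = "other"} with no position; unparseable input is a value,
#' never an error.
#'
#' @param aa_change character vector of protein-change strings.
#' @return data.frame with \code{ref}, \code{pos} (1-based residue index or
#'   NA), \code{alt} and \code{kind} (missense / nonsense / frameshift /
#'   synonymous / other).
#' @examples
#' parse_aa_change(c("p.Y723F", "p.W736*", "p.G12fs", "p.T729T", "?"))
#' @export
parse_aa_change <- function(aa_change) {
  x <- as.character(aa_change)
  n <- length(x)
  out <- data.frame(ref = NA_character_, pos = NA_integer_,
                    alt = NA_character_, kind = "other",
                    stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  if (!n) return(out[0, ])

  fs <- grepl("^p\\.[A-Za-z*][0-9]+fs(\\*[0-9]*)?$", x)
  ns <- grepl("^p\\.[A-Za-z][0-9]+\\*$", x)
  ms <- grepl("^p\\.[A-Za-z][0-9]+[A-Za-z]$", x)

  take <- function(i, pat) sub(pat, "\\1", x[i])
  if (any(fs)) {
    out$ref[fs] <- take(fs, "^p\\.([A-Za-z*]).*$")
    out$pos[fs] <- as.integer(take(fs, "^p\\.[A-Za-z*]([0-9]+)fs.*$"))
    out$alt[fs] <- "fs"
    out$kind[fs] <- "frameshift"
  }
  if (any(ns)) {
    out$ref[ns] <- take(ns, "^p\\.([A-Za-z]).*$")
    out$pos[ns] <- as.integer(take(ns, "^p\\.[A-Za-z]([0-9]+)\\*$"))
    out$alt[ns] <- "*"
    out$kind[ns] <- "nonsense"
  }
  if (any(ms)) {
    out$ref[ms] <- toupper(take(ms, "^p\\.([A-Za-z]).*$"))
    out$pos[ms] <- as.integer(take(ms, "^p\\.[A-Za-z]([0-9]+)[A-Za-z]$"))
    out$alt[ms] <- toupper(take(ms, "^p\\.[A-Za-z][0-9]+([A-Za-z])$"))
    syn <- ms & out$ref == out$alt
    out$kind[ms] <- "missense"
    out$kind[syn] <- "synonymous"
  }
  out
}

#' Classify protein changes into TOP1 domain groups
#'
#' Nonsense and frameshift changes map to \code{"Stop"} wherever they fall in
#' the coding region; missense changes map to the domain containing their
#' residue; synonymous, unparseable and out-of-range changes map to
#' \code{"none"}.
#'
#' @param changes data.frame from [parse_aa_change()] (columns \code{kind},
#'   \code{pos}).
#' @param map domain map, default [top1_domain_map()].
#' @return character vector of group labels.
#' @export
classify_domain <- function(changes, map = top1_domain_map()) {
  map <- check_domain_map(map)
  out <- rep("none", nrow(changes))
  out[changes$kind %in% c("nonsense", "frameshift")] <- "Stop"
  is_ms <- changes$kind == "missense" & !is.na(changes$pos)
  if (any(is_ms)) {
    idx <- findInterval(changes$pos[is_ms], map$aa_lo)
    lab <- rep("none", sum(is_ms))
    ok <- idx >= 1L & changes$pos[is_ms] <= map$aa_hi[pmax(idx, 1L)]
    lab[ok] <- map$domain[idx[ok]]
    out[is_ms] <- lab
  }
  out
}

# Precedence when one sample carries classifiable changes in several groups:
# classes most likely to compromise catalytic function win.
.group_precedence <- c("Stop", "C-Ter", "Linker", "Core", "N-Ter")

#' Assign each sample a TOP1 domain group
#'
#' Parses and classifies every record of \code{gene} and gives each sample
#' carrying at least one classifiable change exactly one group. When a sample
#' has changes in several groups, precedence is
#' Stop > C-Ter > Linker > Core > N-Ter (multi-group samples are reported via
#' \code{message}).
#'
#' @param profiles sample profiles from [per_sample_totals()].
#' @param records mutation records the profiles were built from.
#' @param gene gene symbol whose mutations define the groups (default "TOP1").
#' @param map domain map, default [top1_domain_map()].
#' @return \code{profiles} with \code{top1_group} filled in.
#' @export
assign_top1_groups <- function(profiles, records, gene = "TOP1",
                               map = top1_domain_map()) {
  profiles$top1_group <- "none"
  sel <- records$gene == gene
  if (!any(sel)) return(profiles)
  grp <- classify_domain(parse_aa_change(records$aa_change[sel]), map)
  sid <- records$sample_id[sel]
  keep <- grp != "none"
  if (any(keep)) {
    pick <- tapply(grp[keep], sid[keep], function(g) {
      u <- unique(g)
      .group_precedence[min(match(u, .group_precedence))]
    })
    multi <- tapply(grp[keep], sid[keep], function(g) length(unique(g)) > 1L)
    if (any(multi))
      message("assign_top1_groups: ", sum(multi),
              " sample(s) with changes in several groups resolved by ",
              "precedence Stop > C-Ter > Linker > Core > N-Ter")
    m <- match(profiles$sample_id, names(pick))
    profiles$top1_group[!is.na(m)] <- unname(pick[m[!is.na(m)]])
  }
  profiles
}

#' Pool domain groups into combined sample sets
#'
#' @param profiles profiles with \code{top1_group} assigned.
#' @param pools named list of group-label vectors, e.g.
#'   \code{list(NLC = c("N-Ter", "Linker", "Core"), CS = c("C-Ter", "Stop"))}
#'   (the default). Pools must not share a group label.
#' @return named list of sample-id character vectors, one per pool.
#' @export
combine_groups <- function(profiles,
                           pools = list(NLC = c("N-Ter", "Linker", "Core"),
                                        CS = c("C-Ter", "Stop"))) {
  if (!length(pools)) return(list())
  all_members <- unlist(pools)
  if (anyDuplicated(all_members))
    stop("overlapping pool definitions: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  lapply(pools, function(gs) {
    sort(profiles$sample_id[profiles$top1_group %in% gs])
  })
}

#' Random control set (Ran)
#'
#' Uniform sample of \code{n} sample ids without replacement, seeded and
#' invariant to the input row order (profiles are sorted by id before
#' sampling).
#'
#' @param profiles sample profiles.
#' @param n set size (default 300).
#' @param seed integer seed.
#' @return sorted character vector of sample ids.
#' @export
select_ran <- function(profiles, n = 300L, seed) {
  ids <- sort(unique(profiles$sample_id))
  if (n > length(ids)) stop("n = ", n, " exceeds the ", length(ids),
                            " available samples")
  sort(with_seed(seed, sample(ids, n)))
}

#' High-mutation random control set (Ran_H)
#'
#' Two-stage seeded selection: a uniform pool of up to \code{pool_size}
#' samples is drawn from those with at least \code{min_mut} mutations, sample
#' codes shared by pool members of different tumor types are removed, then
#' \code{n} entries are drawn uniformly from the pool.
#'
#' @param profiles sample profiles.
#' @param min_mut minimum total mutations to qualify (default 400).
#' @param pool_size first-stage pool size (default 1500). When fewer samples
#'   qualify, the pool is all qualifying samples (reported via message).
#' @param n final set size (default 300).
#' @param seed integer seed.
#' @return sorted character vector of sample ids.
#' @export
select_ran_high <- function(profiles, min_mut = 400L, pool_size = 1500L,
                            n = 300L, seed) {
  qual <- profiles[profiles$total_mutations >= min_mut, , drop = FALSE]
  qual <- qual[order(qual$sample_id), , drop = FALSE]
  if (nrow(qual) < n)
    stop("only ", nrow(qual), " samples have >= ", min_mut,
         " mutations; cannot select ", n)
  with_seed(seed, {
    pool_ids <- if (nrow(qual) > pool_size) sample(qual$sample_id, pool_size)
                else {
                  message("select_ran_high: only ", nrow(qual),
                          " qualifying samples; pool is all of them")
                  qual$sample_id
                }
    pool <- qual[match(sort(pool_ids), qual$sample_id), , drop = FALSE]
    tt <- tapply(pool$tumor_type, pool$sample_code,
                 function(x) length(unique(x)))
    bad <- names(tt)[tt > 1L]
    pool <- pool[!(pool$sample_code %in% bad), , drop = FALSE]
    if (nrow(pool) < n)
      stop("pool too small after removing ambiguous sample codes")
    sort(sample(pool$sample_id, n))
  })
}
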