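#' Search parameters for compensatory indel sets
#'
#' Defaults encode the published search restrictions: each indel shorter
#' than five bases and not a multiple of three (conditions i-ii), the
#' combined length change a multiple of three (condition iii, with the
#' one-codon-shifted sums -3 and +3 accepted alongside 0), all members
#' within 20 base pairs (condition iv), at most 10 indels per set and at
#' most 20 reported sets per valid sum.
#'
#' @param max_set_size Maximum members per set.
#' @param max_sets_per_sum Cap on reported sets per valid net sum.
#' @param window Base-pair window (condition iv).
#' @param max_indel_len Maximum |length change| per indel.
#' @param valid_sums Admissible net length changes.
#' @param window_mode `"span"` (default): leftmost-to-rightmost distance
#'   of the set is at most `window`; `"anchor"`: every member lies within
#'   `window` of the target.
#' @return A list of class `search_params`.
#' @export
search_params <- function(max_set_size = 10L, max_sets_per_sum = 20L,
                          window = 20L, max_indel_len = 4L,
                          valid_sums = c(-3L, 0L, 3L),
                          window_mode = c("span", "anchor")) {
  window_mode <- match.arg(window_mode)
  stopifnot(max_set_size >= 2, max_sets_per_sum >= 1, window >= 1,
            max_indel_len >= 1, length(valid_sums) >= 1)
  structure(list(max_set_size = as.integer(max_set_size),
                 max_sets_per_sum = as.integer(max_sets_per_sum),
                 window = as.integer(window),
                 max_indel_len = as.integer(max_indel_len),
                 valid_sums = as.integer(valid_sums),
                 window_mode = window_mode),
            class = "search_params")
}

#' Normalise an indel catalog
#'
#' An indel catalog is a data frame with `id`, `pos` (coding coordinate)
#' and `delta` (signed length change, insertions positive); `delta` may
#' instead be derived from `ref`/`alt` columns.
#'
#' @param catalog Data frame.
#' @return Validated data frame with `id`, `pos`, `delta`.
#' @export
as_indel_catalog <- function(catalog) {
  if (!is.data.frame(catalog))
    stop("catalog must be a data frame", call. = FALSE)
  if (!"delta" %in% names(catalog)) {
    if (!all(c("ref", "alt") %in% names(catalog)))
      stop("catalog needs a delta column or ref/alt columns",
           call. = FALSE)
    catalog$delta <- nchar(as.character(catalog$alt)) -
      nchar(as.character(catalog$ref))
  }
  if (!all(c("pos") %in% names(catalog)))
    stop("catalog needs a pos column", call. = FALSE)
  if (is.null(catalog$id))
    catalog$id <- paste0("indel", seq_len(nrow(catalog)))
  catalog$id <- as.character(catalog$id)
  catalog$pos <- as.integer(catalog$pos)
  catalog$delta <- as.integer(catalog$delta)
  if (anyDuplicated(catalog$id))
    stop("catalog ids must be unique", call. = FALSE)
  if (any(catalog$delta == 0L))
    stop("catalog rows with delta 0 are not indels", call. = FALSE)
  catalog[, c("id", "pos", "delta")]
}

#' Admission filter for compensatory-set candidates
#'
#' An indel can participate in a compensatory set iff its length change
#' is below five bases in magnitude and not divisible by three (a
#' frame-shifting short indel).
#'
#' @param delta Signed length change(s).
#' @param params A [search_params()].
#' @return Logical vector.
#' @examples
#' admit_indel(c(1, -2, 3, -5, 4))   # TRUE TRUE FALSE FALSE TRUE
#' @export
admit_indel <- function(delta, params = search_params()) {
  delta <- as.integer(delta)
  delta != 0L & abs(delta) <= params$max_indel_len &
    delta %% 3L != 0L
}

#' Enumerate compensatory indel sets for a target indel
#'
#' Finds subsets of the catalog that contain the target indel, satisfy
#' the admission filters, lie within the base-pair window, have at most
#' `max_set_size` members and a net length change in `valid_sums` - the
#' frame-preserving combinations that can rescue the target frameshift.
#' The search is a windowed bounded subset-sum enumeration over the
#' position-sorted candidates, expanding bracketing (leftmost,
#' rightmost) pairs in order of increasing span and interior subsets in
#' order of increasing size, so sets are produced directly in the
#' deterministic ranking (span ascending, then size, then member ids)
#' and enumeration can stop as soon as every valid sum has
#' `max_sets_per_sum` sets.
#'
#' @param target_id Id of the target indel (must be in the catalog and
#'   pass [admit_indel()]).
#' @param catalog An indel catalog ([as_indel_catalog()]).
#' @param params A [search_params()].
#' @param cap Apply the per-sum cap (default).  With `cap = FALSE` the
#'   complete pre-cap enumeration is returned (refused for more than 16
#'   windowed candidates).
#' @return Data frame with one row per set: `target_id`, `members`
#'   (semicolon-joined ids, position order), `size`, `net_delta`,
#'   `span`; ordered by (span, size, members).
#' @export
find_compensatory_sets <- function(target_id, catalog,
                                   params = search_params(),
                                   cap = TRUE) {
  catalog <- as_indel_catalog(catalog)
  ti <- match(as.character(target_id), catalog$id)
  if (is.na(ti))
    stop("target ", target_id, " not found in catalog", call. = FALSE)
  target <- catalog[ti, ]
  if (!admit_indel(target$delta, params))
    stop("target ", target_id, " fails the admission filter ",
         "(|delta| <= ", params$max_indel_len,
         ", delta not divisible by 3)", call. = FALSE)

  cand <- catalog[admit_indel(catalog$delta, params) &
                    abs(catalog$pos - target$pos) <= params$window, ,
                  drop = FALSE]
  cand <- cand[order(cand$pos, cand$id), , drop = FALSE]
  n <- nrow(cand)
  empty <- data.frame(target_id = character(), members = character(),
                      size = integer(), net_delta = integer(),
                      span = integer())
  if (n < 2L) return(empty)
  if (!cap && n > 16L)
    stop("pre-cap enumeration limited to 16 windowed candidates",
         call. = FALSE)
  t_idx <- which(cand$id == target$id)

  span_check <- params$window_mode == "span"
  # bracketing index pairs (l < r) that can contain the target
  pairs <- expand.grid(l = seq_len(n), r = seq_len(n))
  pairs <- pairs[pairs$l < pairs$r &
                   pairs$l <= t_idx & t_idx <= pairs$r, , drop = FALSE]
  pairs$span <- cand$pos[pairs$r] - cand$pos[pairs$l]
  if (span_check) pairs <- pairs[pairs$span <= params$window, ,
                                 drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pairs <- pairs[order(pairs$span, pairs$l, pairs$r), , drop = FALSE]

  quota <- if (cap) params$max_sets_per_sum else Inf
  got <- stats::setNames(rep(0L, length(params$valid_sums)),
                         params$valid_sums)
  out <- list()
  expansions <- 0L
  max_expansions <- 2e6

  for (sp in unique(pairs$span)) {
    grp <- pairs[pairs$span == sp, , drop = FALSE]
    # all sets of one span group, produced size-ascending
    for (size in 2:params$max_set_size) {
      if (all(got >= quota)) break
      rows <- list()
      for (pi in seq_len(nrow(grp))) {
        l <- grp$l[pi]; r <- grp$r[pi]
        base <- unique(c(l, r, t_idx))
        base <- base[base >= l & base <= r]
        free <- setdiff(seq(l, r), base)
        k <- size - length(base)
        if (k < 0 || k > length(free)) next
        combos <- if (k == 0L) list(integer(0))
          else lapply(utils::combn(seq_along(free), k,
                                   simplify = FALSE),
                      function(j) free[j])
        expansions <- expansions + length(combos)
        if (expansions > max_expansions) {
          warning("compensatory-set enumeration truncated after ",
                  max_expansions, " expansions; per-sum ranking may be ",
                  "incomplete")
          break
        }
        for (cset in combos) {
          idx <- sort(unique(c(base, cset)))
          net <- sum(cand$delta[idx])
          if (!net %in% params$valid_sums) next
          rows[[length(rows) + 1L]] <- list(
            idx = idx, net = net,
            members = paste(cand$id[idx], collapse = ";"))
        }
      }
      if (length(rows)) {
        ord <- order(vapply(rows, `[[`, character(1), "members"))
        for (rw in rows[ord]) {
          sk <- as.character(rw$net)
          if (got[[sk]] >= quota) next
          got[[sk]] <- got[[sk]] + 1L
          out[[length(out) + 1L]] <- data.frame(
            target_id = target$id, members = rw$members,
            size = length(rw$idx), net_delta = rw$net, span = sp)
        }
      }
      if (expansions > max_expansions) break
    }
    if (all(got >= quota) || expansions > max_expansions) break
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$span, res$size, res$members), , drop = FALSE] ->
    res
  rownames(res) <- NULL
  res
}

#' Exhaustive compensatory-set enumeration (test oracle)
#'
#' Enumerates every subset of the windowed, admitted catalog that
#' contains the target and checks the four search conditions directly;
#' no per-sum cap is applied.  Refuses more than 15 windowed candidates.
#' Exists as an independent check on [find_compensatory_sets()].
#'
#' @inheritParams find_compensatory_sets
#' @return Data frame in the same shape and order as
#'   [find_compensatory_sets()] with `cap = FALSE`.
#' @export
brute_force_sets <- function(target_id, catalog,
                             params = search_params()) {
  catalog <- as_indel_catalog(catalog)
  ti <- match(as.character(target_id), catalog$id)
  if (is.na(ti))
    stop("target ", target_id, " not found in catalog", call. = FALSE)
  target <- catalog[ti, ]
  if (!admit_indel(target$delta, params))
    stop("target fails the admission filter", call. = FALSE)
  cand <- catalog[admit_indel(catalog$delta, params) &
                    abs(catalog$pos - target$pos) <= params$window, ,
                  drop = FALSE]
  cand <- cand[order(cand$pos, cand$id), , drop = FALSE]
  n <- nrow(cand)
  if (n > 15L)
    stop("brute-force oracle limited to 15 windowed candidates",
         call. = FALSE)
  t_idx <- which(cand$id == target$id)
  others <- setdiff(seq_len(n), t_idx)
  rows <- list()
  for (mask in 0:(2^length(others) - 1L)) {
    sel <- others[bitwAnd(mask, bitwShiftL(1L, seq_along(others) - 1L)) != 0L]
    idx <- sort(c(t_idx, sel))
    size <- length(idx)
    if (size < 2L || size > params$max_set_size) next
    net <- sum(cand$delta[idx])
    if (!net %in% params$valid_sums) next
    span <- max(cand$pos[idx]) - min(cand$pos[idx])
    if (params$window_mode == "span") {
      if (span > params$window) next
    } else {
      if (any(abs(cand$pos[idx] - target$pos) > params$window)) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      target_id = target$id,
      members = paste(cand$id[idx], collapse = ";"),
      size = size, net_delta = net, span = span)
  }
  if (!length(rows))
    return(data.frame(target_id = character(), members = character(),
                      size = integer(), net_delta = integer(),
                      span = integer()))
  res <- do.call(rbind, rows)
  res <- res[order(res$span, res$size, res$members), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write compensatory sets to TSV
#'
#' @param sets Result of [find_compensatory_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compensatory_tsv <- function(sets, path) {
  utils::write.table(sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
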