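# Classification geometry.
#
# All rules are evaluated in offset space: for an insert starting at s, a
# feature at genome position x has offset o = (x - s) mod G (circular) or
# o = x - s (linear); the feature lies in the insert iff 0 <= o < L.
# Orientation A transcribes toward increasing offset (reporter beyond offset
# L - 1); orientation B toward decreasing offset (reporter beyond offset 0).
# A sense promoter at offset o_p fires iff no sense terminator lies strictly
# between it and the reporter-proximal insert end:
#   A: no terminator with o_p < o_t < L
#   B: no terminator with 0 < o_t < o_p
# so a terminator exactly at the reporter-proximal boundary (offset 0 in
# orientation B; the half-open end is outside the insert in orientation A)
# never blocks. In upstream_promoter mode the vector promoter must traverse
# the whole insert, and the rule is presence-based: any sense terminator in
# the insert blocks.

# Per-orientation sense-strand feature tables with terminator clearances:
# clear = distance (in transcription direction) from each promoter to the
# nearest strictly-downstream sense terminator (Inf when none), plus the id
# of that terminator.
.sense_features <- function(genome, orientation) {
  strand <- if (orientation == "A") "+" else "-"
  pr <- promoters_of(genome)
  tm <- terminators_of(genome)
  pr <- pr[pr$strand == strand, , drop = FALSE]
  tm <- tm[tm$strand == strand, , drop = FALSE]
  ord <- order(tm$position)
  tpos <- tm$position[ord]; tid <- tm$id[ord]; trho <- tm$read_through[ord]
  G <- genome$length
  n <- nrow(pr)
  clear <- rep(Inf, n); clear_tid <- rep(NA_character_, n)
  if (length(tpos) > 0 && n > 0) {
    if (orientation == "A") {
      # first terminator strictly after p (wrapping if circular)
      i <- findInterval(pr$position, tpos) + 1L   # first tpos > p (ties: after)
      # findInterval gives count of tpos <= p, so tpos[i] > p strictly
      wrap <- i > length(tpos)
      d <- ifelse(wrap, NA, tpos[pmin(i, length(tpos))] - pr$position)
      if (genome$circular) {
        d[wrap] <- tpos[1] + G - pr$position[wrap]
        clear_tid <- ifelse(wrap, tid[1], tid[pmin(i, length(tpos))])
      } else {
        clear_tid <- ifelse(wrap, NA_character_, tid[pmin(i, length(tpos))])
      }
      clear <- ifelse(is.na(d), Inf, d)
    } else {
      # first terminator strictly before p
      i <- findInterval(pr$position - 0.5, tpos)  # count of tpos < p
      none <- i < 1L
      d <- ifelse(none, NA, pr$position - tpos[pmax(i, 1L)])
      if (genome$circular) {
        d[none] <- pr$position[none] + G - tpos[length(tpos)]
        clear_tid <- ifelse(none, tid[length(tpos)], tid[pmax(i, 1L)])
      } else {
        clear_tid <- ifelse(none, NA_character_, tid[pmax(i, 1L)])
      }
      clear <- ifelse(is.na(d), Inf, d)
    }
  }
  list(prom = data.frame(id = pr$id, pos = pr$position, clear = clear,
                         clear_tid = clear_tid, stringsAsFactors = FALSE),
       term = data.frame(id = tid, pos = tpos, rho = trho,
                         stringsAsFactors = FALSE))
}

# (insert, feature) pairs for sorted feature positions falling inside each
# window [s_i, s_i + L_i), with wraparound on circular genomes.
.window_pairs <- function(pos, s, L, G, circular) {
  e <- s + L
  i1 <- findInterval(s - 0.5, pos) + 1L
  i2 <- findInterval(pmin(e, G) - 0.5, pos)
  cnt <- pmax(0L, i2 - i1 + 1L)
  ins <- rep(seq_along(s), cnt)
  fid <- unlist(lapply(which(cnt > 0), function(i) i1[i]:i2[i]),
                use.names = FALSE)
  if (circular && any(e > G)) {
    w <- which(e > G)
    j2 <- findInterval(e[w] - G - 0.5, pos)
    cnt2 <- pmax(0L, j2)
    ins2 <- rep(w, cnt2)
    fid2 <- unlist(lapply(which(cnt2 > 0), function(k) seq_len(j2[k])),
                   use.names = FALSE)
    ins <- c(ins, ins2); fid <- c(fid, as.integer(fid2))
  }
  list(insert = ins, feature = as.integer(fid))
}

#' Classify sheared inserts for reporter expression
#'
#' Applies the trap rules to every insert: in `promoterless` mode an insert
#' is GFP-positive iff a recognized sense-strand promoter inside it has a
#' terminator-free path to the reporter-proximal end; in `upstream_promoter`
#' mode iff no sense-strand terminator lies in the insert (with
#' `internal_rescue`, a recognized internal promoter with a clear path also
#' scores positive). When several promoters can fire, the reported cause is
#' the reporter-proximal-most one. Terminators with `read_through > 0` block
#' stochastically (each with probability `1 - read_through`, drawn from
#' `seed`); the default annotation has absolute termination and the
#' classification is then deterministic.
#'
#' @param inserts `data.frame` from [shear()] (`start`, `length`,
#'   `orientation`).
#' @param genome A `genome_annotation`.
#' @param mode A [vector_mode()].
#' @param sigma A [sigma_model()].
#' @param seed Seed for stochastic read-through draws (only consulted when
#'   some terminator has `read_through > 0`).
#' @return `data.frame` with columns `gfp_positive`, `cause`
#'   (`"promoter_fired"`, `"read_through"`, `"none"`), `promoter_id`,
#'   `blocking_terminator`.
#' @export
classify_inserts <- function(inserts, genome, mode, sigma, seed = 1) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(mode, "vector_mode"), inherits(sigma, "sigma_model"))
  G <- genome$length
  s <- inserts$start; L <- inserts$length
  if (any(s < 0 | s >= G)) stop("insert start outside genome")
  if (any(L < 1 | L > G)) stop("insert length outside [1, genome length]")
  if (!genome$circular && any(s + L > G))
    stop("insert wraps on a linear genome")
  rec <- materialize_recognition(sigma, genome)
  rho_used <- any(terminators_of(genome)$read_through > 0)
  n <- nrow(inserts)
  gfp <- logical(n)
  cause <- rep("none", n)
  pid <- rep(NA_character_, n)
  bterm <- rep(NA_character_, n)

  run <- function() {
    for (orient in c("A", "B")) {
      idx <- which(inserts$orientation == orient)
      if (!length(idx)) next
      sf <- .sense_features(genome, orient)
      si <- s[idx]; Li <- L[idx]
      prom <- sf$prom
      prom_rec <- rec[prom$id]
      ## promoter candidates inside each window
      pp <- .window_pairs(prom$pos, si, Li, G, genome$circular)
      if (length(pp$insert)) {
        o_p <- (prom$pos[pp$feature] - si[pp$insert]) %% G
        fires <- prom_rec[pp$feature] &
          (if (orient == "A") o_p + prom$clear[pp$feature] >= Li[pp$insert]
           else o_p <= prom$clear[pp$feature])
        if (rho_used) {
          # a blocked promoter still fires if every intervening terminator
          # reads through; draws are independent per (insert, promoter)
          blocked <- which(prom_rec[pp$feature] & !fires)
          for (k in blocked) {
            tset <- sf$term
            o_t <- (tset$pos - si[pp$insert[k]]) %% G
            between <- if (orient == "A")
              o_t > o_p[k] & o_t < Li[pp$insert[k]] else o_t > 0 & o_t < o_p[k]
            if (all(stats::runif(sum(between)) < tset$rho[between]))
              fires[k] <- TRUE
          }
        }
      } else {
        o_p <- numeric(0); fires <- logical(0)
      }
      ## reporter-proximal-most firing promoter per insert
      if (any(fires)) {
        key <- if (orient == "A") -o_p[fires] else o_p[fires]
        ordk <- order(pp$insert[fires], key)
        ins_f <- pp$insert[fires][ordk]
        feat_f <- pp$feature[fires][ordk]
        first <- !duplicated(ins_f)
        fired_ins <- ins_f[first]
        fired_feat <- feat_f[first]
      } else {
        fired_ins <- integer(0); fired_feat <- integer(0)
      }
      if (mode$kind == "promoterless") {
        gi <- idx[fired_ins]
        gfp[gi] <<- TRUE
        cause[gi] <<- "promoter_fired"
        pid[gi] <<- prom$id[fired_feat]
        ## blocked candidate: reporter-proximal-most recognized promoter of a
        ## negative insert, with the terminator that stops it
        neg <- which(!(seq_along(idx) %in% fired_ins))
        if (length(pp$insert)) {
          cand <- prom_rec[pp$feature] & pp$insert %in% neg
          if (any(cand)) {
            keyc <- if (orient == "A") -o_p[cand] else o_p[cand]
            ordc <- order(pp$insert[cand], keyc)
            insc <- pp$insert[cand][ordc]; featc <- pp$feature[cand][ordc]
            firstc <- !duplicated(insc)
            bterm[idx[insc[firstc]]] <<- prom$clear_tid[featc[firstc]]
          }
        }
      } else {
        ## upstream promoter: presence of any sense terminator blocks
        tp <- .window_pairs(sf$term$pos, si, Li, G, genome$circular)
        ntt <- tabulate(tp$insert, nbins = length(idx))
        blocked <- ntt > 0
        if (rho_used && any(blocked)) {
          for (i in which(blocked)) {
            rho_i <- sf$term$rho[tp$feature[tp$insert == i]]
            if (all(stats::runif(length(rho_i)) < rho_i)) blocked[i] <- FALSE
          }
        }
        pos_read <- !blocked
        gi <- idx[pos_read]
        gfp[gi] <<- TRUE
        cause[gi] <<- "read_through"
        if (any(blocked)) {
          bl <- which(blocked)
          ## reporter-proximal-most terminator of each blocked insert
          o_t <- (sf$term$pos[tp$feature] - si[tp$insert]) %% G
          keyt <- if (orient == "A") -o_t else o_t
          ordt <- order(tp$insert, keyt)
          inst <- tp$insert[ordt]; featt <- tp$feature[ordt]
          firstt <- !duplicated(inst)
          bterm[idx[inst[firstt]]] <<- sf$term$id[featt[firstt]]
        }
        if (mode$internal_rescue && length(fired_ins)) {
          resc <- fired_ins[blocked[fired_ins]]
          rfeat <- fired_feat[blocked[fired_ins]]
          gi <- idx[resc]
          gfp[gi] <<- TRUE
          cause[gi] <<- "promoter_fired"
          pid[gi] <<- prom$id[rfeat]
          bterm[gi] <<- NA_character_
        }
      }
    }
  }
  if (rho_used) withr::with_seed(as.integer(seed), run()) else run()
  data.frame(gfp_positive = gfp, cause = cause, promoter_id = pid,
             blocking_terminator = bterm, stringsAsFactors = FALSE)
}

#' Classify a single insert
#'
#' Scalar convenience wrapper around [classify_inserts()].
#'
#' @param start,length,orientation Insert coordinates (0-based start, bp
#'   length, `"A"`/`"B"`).
#' @inheritParams classify_inserts
#' @return One-row `data.frame` as in [classify_inserts()].
#' @export
classify_insert <- function(start, length, orientation, genome, mode, sigma,
                            seed = 1) {
  classify_inserts(data.frame(start = start, length = length,
                              orientation = orientation,
                              stringsAsFactors = FALSE),
                   genome, mode, sigma, seed = seed)
}
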