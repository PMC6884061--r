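## Gene models with exon/intron structure, planted variants, and the
## sequence-level mutate-splice-translate reference used to validate the
## rule-based large-effect classifier.

#' Simulate a gene model with exon/intron structure
#'
#' A random CDS (ATG ... stop, no internal in-frame stop) is split into
#' exons by inserting GT..AG introns at random positions; the result is a
#' genomic sequence with an exon coordinate table.
#'
#' @param n_codons number of codons including start and stop
#' @param n_introns number of introns (0 or more)
#' @param intron_len_range integer range introns are drawn from
#' @param seed integer seed
#' @return an object of class `gene_model`: `genomic` (character string),
#'   `exons` (data.frame: start, end, 1-based genomic, ascending),
#'   `introns` (data.frame: start, end), `cds` (spliced CDS string)
#' @export
simulate_gene_model <- function(n_codons = 120, n_introns = 2,
                                intron_len_range = c(60L, 120L),
                                seed = 1L) {
  stopifnot(n_codons >= 10, n_introns >= 0)
  withr::with_seed(as.integer(seed), {
    sense <- .sense_codons()
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons - 2, replace = TRUE),
                        collapse = ""),
                  sample(.STOP_CODONS, 1))
    L <- nchar(cds)
    ## intron insertion points: strictly interior, distinct, away from the
    ## first and last codon
    if (n_introns > 0) {
      pts <- sort(sample(4:(L - 4), n_introns))
      while (any(diff(pts) < 6) && n_introns > 1) {
        pts <- sort(sample(4:(L - 4), n_introns))
      }
    } else {
      pts <- integer(0)
    }
    intron_seqs <- vapply(seq_len(n_introns), function(i) {
      len <- sample(intron_len_range[1]:intron_len_range[2], 1)
      paste0("GT",
             paste(sample(.BASES, len - 4, replace = TRUE), collapse = ""),
             "AG")
    }, "")

    genomic <- ""
    exon_rows <- list(); intron_rows <- list()
    prev <- 0L; gpos <- 0L
    for (i in seq_len(n_introns)) {
      exon_seq <- substr(cds, prev + 1L, pts[i])
      exon_rows[[i]] <- data.frame(start = gpos + 1L,
                                   end = gpos + nchar(exon_seq))
      genomic <- paste0(genomic, exon_seq)
      gpos <- gpos + nchar(exon_seq)
      intron_rows[[i]] <- data.frame(start = gpos + 1L,
                                     end = gpos + nchar(intron_seqs[i]))
      genomic <- paste0(genomic, intron_seqs[i])
      gpos <- gpos + nchar(intron_seqs[i])
      prev <- pts[i]
    }
    exon_seq <- substr(cds, prev + 1L, L)
    exon_rows[[n_introns + 1L]] <- data.frame(start = gpos + 1L,
                                              end = gpos + nchar(exon_seq))
    genomic <- paste0(genomic, exon_seq)

    structure(list(genomic = genomic,
                   exons = do.call(rbind, exon_rows),
                   introns = .rbind_or_empty(intron_rows, c("start", "end")),
                   cds = cds),
              class = "gene_model")
  })
}

#' Plant a variant of a requested class in a gene model
#'
#' Constructs a variant whose rule-based consequence is known by
#' construction.  Neutral exonic substitutions preserve codon sense;
#' frame-preserving insertions are whole sense codons at codon boundaries
#' and frame-preserving deletions remove whole interior codons, so neither
#' creates a premature stop.
#'
#' @param model a `gene_model`
#' @param class one of `"none_exon_sub"`, `"none_intron_sub"`,
#'   `"frameshift_ins"`, `"frameshift_del"`, `"frame_preserving_ins"`,
#'   `"frame_preserving_del"`, `"premature_stop"`, `"stop_loss"`,
#'   `"start_loss"`, `"splice_donor"`, `"splice_acceptor"`
#' @param seed integer seed
#' @return a list variant: `pos` (1-based genomic), `type` (`sub`, `ins`,
#'   `del`), `ref`, `alt` (sub) or `length`/`inserted_seq` (indel), and the
#'   intended `class`; `NULL` if the class cannot be planted in this model
#' @export
plant_variant <- function(model, class, seed = 1L) {
  gchars <- .str_to_chars(model$genomic)
  cds_chars <- .str_to_chars(model$cds)
  L <- nchar(model$cds)
  ## map CDS coordinate -> genomic coordinate
  cds2g <- integer(L)
  k <- 0L
  for (i in seq_len(nrow(model$exons))) {
    idx <- model$exons$start[i]:model$exons$end[i]
    cds2g[(k + 1L):(k + length(idx))] <- idx
    k <- k + length(idx)
  }
  sub_at <- function(cds_pos, alt) {
    list(pos = cds2g[cds_pos], type = "sub", ref = cds_chars[cds_pos],
         alt = alt, class = class)
  }
  withr::with_seed(as.integer(seed), {
    out <- switch(class,
      none_exon_sub = {
        for (try in 1:50) {
          p <- sample(4:(L - 3), 1)
          alts <- .sense_alts(cds_chars, p)
          if (length(alts) > 0) return(sub_at(p, sample(alts, 1)))
        }
        NULL
      },
      none_intron_sub = {
        if (nrow(model$introns) == 0L) return(NULL)
        i <- sample.int(nrow(model$introns), 1)
        s <- model$introns$start[i]; e <- model$introns$end[i]
        if (e - s < 6) return(NULL)
        p <- sample((s + 2L):(e - 2L), 1)
        list(pos = p, type = "sub", ref = gchars[p],
             alt = sample(setdiff(.BASES, gchars[p]), 1), class = class)
      },
      frameshift_ins = {
        p <- .exon_interior_point(model, cds2g, L)
        if (is.null(p)) return(NULL)
        len <- sample(c(1L, 2L, 4L, 5L), 1)
        list(pos = p, type = "ins", length = len,
             inserted_seq = paste(sample(.BASES, len, replace = TRUE),
                                  collapse = ""),
             class = class)
      },
      frameshift_del = {
        d <- .exon_interior_window(model, cds2g, L,
                                   sample(c(1L, 2L, 4L), 1))
        if (is.null(d)) return(NULL)
        c(d, list(class = class))
      },
      frame_preserving_ins = {
        ## whole sense codons inserted at a codon boundary
        ci <- sample(2:(L / 3 - 1), 1)
        cds_pos <- (ci - 1L) * 3L  # after this CDS position
        g <- cds2g[cds_pos]
        ## boundary must be intra-exon (next CDS base contiguous in genome)
        if (cds2g[cds_pos + 1L] != g + 1L) return(NULL)
        n_cod <- sample(1:2, 1)
        ins <- paste(sample(.sense_codons(), n_cod, replace = TRUE),
                     collapse = "")
        list(pos = g, type = "ins", length = nchar(ins),
             inserted_seq = ins, class = class)
      },
      frame_preserving_del = {
        ## delete whole interior codons lying inside one exon
        for (try in 1:50) {
          n_cod <- sample(1:2, 1)
          ci <- sample(2:(L / 3 - n_cod), 1)
          cds_from <- (ci - 1L) * 3L + 1L
          cds_to <- cds_from + 3L * n_cod - 1L
          gfrom <- cds2g[cds_from]; gto <- cds2g[cds_to]
          if (gto - gfrom == cds_to - cds_from) {
            return(list(pos = gfrom, type = "del",
                        length = 3L * n_cod, class = class))
          }
        }
        NULL
      },
      premature_stop = {
        plan <- .plan_large_effect(cds_chars, L, "premature_stop", integer(0))
        if (is.null(plan)) return(NULL)
        sub_at(plan$pos, plan$alt)
      },
      stop_loss = {
        plan <- .plan_large_effect(cds_chars, L, "stop_loss", integer(0))
        if (is.null(plan)) return(NULL)
        sub_at(plan$pos, plan$alt)
      },
      start_loss = {
        plan <- .plan_large_effect(cds_chars, L, "start_loss", integer(0))
        sub_at(plan$pos, plan$alt)
      },
      splice_donor = {
        if (nrow(model$introns) == 0L) return(NULL)
        i <- sample.int(nrow(model$introns), 1)
        p <- model$introns$start[i] + sample(0:1, 1)
        list(pos = p, type = "sub", ref = gchars[p],
             alt = sample(setdiff(.BASES, gchars[p]), 1), class = class)
      },
      splice_acceptor = {
        if (nrow(model$introns) == 0L) return(NULL)
        i <- sample.int(nrow(model$introns), 1)
        p <- model$introns$end[i] - sample(0:1, 1)
        list(pos = p, type = "sub", ref = gchars[p],
             alt = sample(setdiff(.BASES, gchars[p]), 1), class = class)
      },
      stop("unknown variant class: ", class)
    )
    out
  })
}

## an exon-interior genomic insertion point away from the first/last codon,
## with room so indels do not touch exon boundaries
.exon_interior_point <- function(model, cds2g, L) {
  for (try in 1:50) {
    p_cds <- sample(4:(L - 4), 1)
    g <- cds2g[p_cds]
    if (cds2g[p_cds + 1L] == g + 1L) return(g)
  }
  NULL
}

.exon_interior_window <- function(model, cds2g, L, len) {
  for (try in 1:50) {
    p_cds <- sample(4:(L - 3 - len), 1)
    gfrom <- cds2g[p_cds]; gto <- cds2g[p_cds + len - 1L]
    if (gto - gfrom == len - 1L) {
      return(list(pos = gfrom, type = "del", length = len))
    }
  }
  NULL
}

#' Rule-based large-effect classification of a variant
#'
#' Positional rules on the gene model: a CDS indel whose length is not a
#' multiple of 3 is a `frameshift`; a substitution creating an in-frame stop
#' 5' of the annotated stop is a `premature_stop`; a substitution turning
#' the annotated stop into a sense codon is a `stop_loss`; any change to the
#' ATG is a `start_loss`; a variant in the first or last 2 nt of an intron
#' is a `splice_disruption`; anything else is `none`.
#'
#' @param variant a variant list as produced by [plant_variant()] (`pos`,
#'   `type`, and `alt` or `length`)
#' @param model a `gene_model`
#' @return one of `"none"`, `"frameshift"`, `"premature_stop"`,
#'   `"stop_loss"`, `"start_loss"`, `"splice_disruption"`
#' @export
classify_effect <- function(variant, model) {
  pos <- variant$pos
  glen <- nchar(model$genomic)
  if (pos < 1L || pos > glen) stop("variant position outside the gene model")

  ## intron?
  if (nrow(model$introns) > 0L) {
    for (i in seq_len(nrow(model$introns))) {
      s <- model$introns$start[i]; e <- model$introns$end[i]
      if (pos >= s && pos <= e) {
        if (pos <= s + 1L || pos >= e - 1L) return("splice_disruption")
        return("none")
      }
    }
  }

  ## exon: map to CDS coordinate
  cds_pos <- 0L
  found <- FALSE
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (pos >= s && pos <= e) {
      cds_pos <- cds_pos + (pos - s + 1L)
      found <- TRUE
      break
    }
    cds_pos <- cds_pos + (e - s + 1L)
  }
  if (!found) stop("variant position outside the gene model")

  L <- nchar(model$cds)
  if (variant$type %in% c("ins", "del")) {
    if (variant$length %% 3L != 0L) return("frameshift")
    return("none")
  }

  ## substitution
  if (cds_pos <= 3L) return("start_loss")
  cds_chars <- .str_to_chars(model$cds)
  if (cds_pos > L - 3L) {
    cod <- cds_chars[(L - 2L):L]
    cod[cds_pos - (L - 3L)] <- variant$alt
    if (!(paste(cod, collapse = "") %in% .STOP_CODONS)) return("stop_loss")
    return("none")
  }
  cod_start <- cds_pos - ((cds_pos - 1L) %% 3L)
  cod <- cds_chars[cod_start:(cod_start + 2L)]
  cod[cds_pos - cod_start + 1L] <- variant$alt
  if (paste(cod, collapse = "") %in% .STOP_CODONS) return("premature_stop")
  "none"
}

#' Sequence-level consequence reference (mutate, splice, translate)
#'
#' Independent of the positional rules in [classify_effect()]: applies the
#' variant to the genomic sequence, splices out every intron whose GT/AG
#' dinucleotides remain intact (a broken signal retains the intron),
#' translates the resulting CDS with the standard code, and classifies by
#' comparing the outcome to the reference protein.
#'
#' @inheritParams classify_effect
#' @return the same effect vocabulary as [classify_effect()]
#' @export
effect_oracle <- function(variant, model) {
  g <- .str_to_chars(model$genomic)
  shift <- 0L
  if (variant$type == "sub") {
    g[variant$pos] <- variant$alt
  } else if (variant$type == "ins") {
    g <- append(g, .str_to_chars(variant$inserted_seq), after = variant$pos)
    shift_at <- variant$pos
    shift <- variant$length
  } else {
    g <- g[-(variant$pos:(variant$pos + variant$length - 1L))]
    shift_at <- variant$pos
    shift <- -variant$length
  }
  adj <- function(p) {
    if (variant$type == "sub") return(p)
    if (p > shift_at) p + shift else p
  }

  ## splice: drop introns with intact signals, retain broken ones
  mutated <- paste(g, collapse = "")
  keep_mask <- rep(TRUE, length(g))
  splice_changed <- FALSE
  if (nrow(model$introns) > 0L) {
    for (i in seq_len(nrow(model$introns))) {
      s <- adj(model$introns$start[i]); e <- adj(model$introns$end[i])
      donor <- paste(g[s:(s + 1L)], collapse = "")
      acceptor <- paste(g[(e - 1L):e], collapse = "")
      if (donor == "GT" && acceptor == "AG") {
        keep_mask[s:e] <- FALSE
      } else {
        splice_changed <- TRUE
      }
    }
  }
  if (splice_changed) return("splice_disruption")
  cds_mut <- paste(g[keep_mask], collapse = "")

  L_ref <- nchar(model$cds)
  if ((nchar(cds_mut) - L_ref) %% 3L != 0L) return("frameshift")
  if (substr(cds_mut, 1L, 3L) != "ATG") return("start_loss")

  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_mut),
                                           no.init.codon = TRUE))
  n_aa <- nchar(aa)
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  has_stop <- stops[1] != -1L
  if (has_stop && min(stops) < n_aa) return("premature_stop")
  if (!has_stop || substr(aa, n_aa, n_aa) != "*") return("stop_loss")
  "none"
}
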