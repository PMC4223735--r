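# Codon counting over the 13 protein-coding genes and chi-square tests
# for deviation of glutamine (CAA/CAG) and glutamate (GAA/GAG) codon usage
# from a reference-panel average.

#' Count codons over a set of protein-coding genes
#'
#' Tallies codons 5' to 3' over in-frame coding sequences. Terminal stop
#' codons — complete (TAA, TAG, AGA, AGG) or incomplete (trailing T or TA
#' completed by polyadenylation) — are excluded from the totals. An
#' optional mask restricts counting to stated codon positions per gene,
#' mirroring analyses confined to alignable regions.
#'
#' @param cds_set A character vector of CDS sequences, or a tibble with
#'   columns `label` and `seq`.
#' @param species Species label attached to the result.
#' @param mask Optional list (one integer vector per CDS) of codon indices
#'   to count.
#' @return A `mito_codon_counts` tibble with one row per codon (`codon`,
#'   `count`) carrying `species`, `caa`, `cag`, `gaa`, `gag`, `total` as
#'   attributes; use [glance()] for the summary row.
#' @export
count_codons <- function(cds_set, species = "sample", mask = NULL) {
  seqs <- if (is.data.frame(cds_set)) cds_set$seq else cds_set
  if (length(seqs) == 0L) abort("no coding sequences supplied")
  stops <- mito_stop_codons()
  all_codons <- character(0)
  for (i in seq_along(seqs)) {
    s <- str_to_upper(seqs[i])
    if (nchar(s) < 3L) abort("CDS shorter than one codon")
    n <- nchar(s) %/% 3L
    trailing <- nchar(s) - 3L * n
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    # drop the terminal stop: complete when the last full codon is a stop
    # and nothing trails; incomplete stops are the trailing T / TA
    if (trailing == 0L && n > 0L && codons[n] %in% stops) {
      codons <- codons[-n]
    }
    if (grepl("[^ACGT]", paste(codons, collapse = ""))) {
      abort("CDS contains ambiguous bases inside the reading frame")
    }
    if (!is.null(mask)) {
      idx <- mask[[i]]
      codons <- codons[idx[idx <= length(codons)]]
    }
    all_codons <- c(all_codons, codons)
  }
  bases <- c("A", "C", "G", "T")
  codon_space <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  counts <- table(factor(all_codons, levels = sort(codon_space)))
  out <- tibble(codon = names(counts), count = as.integer(counts))
  attr(out, "species") <- species
  attr(out, "summary") <- tibble(
    species = species,
    caa = out$count[out$codon == "CAA"],
    cag = out$count[out$codon == "CAG"],
    gaa = out$count[out$codon == "GAA"],
    gag = out$count[out$codon == "GAG"],
    total = sum(out$count)
  )
  class(out) <- c("mito_codon_counts", class(out))
  out
}

#' @method glance mito_codon_counts
#' @export
glance.mito_codon_counts <- function(x, ...) attr(x, "summary")

#' Reference-panel codon-usage averages for geckos
#'
#' Mean counts of the glutamine and glutamate codons over the alignable
#' regions of the 13 protein-coding genes, averaged across a 17-species
#' gecko panel, together with the per-species counts printed for the four
#' newly determined taxa used in the worked examples.
#'
#' @return A list with `panel` (one-row tibble: `caa`, `cag`, `gaa`,
#'   `gag`, `total`, `n_species`) and `species` (four-row tibble of
#'   per-species counts).
#' @export
gecko_codon_panel <- function() {
  list(
    panel = tibble(caa = 69.5, cag = 12.0, gaa = 58.9, gag = 16.8,
                   total = 3441.0, n_species = 17L),
    species = tibble(
      species = c("Tropiocolotes tripolitanus", "Tropiocolotes steudneri",
                  "Uroplatus fimbriatus", "Uroplatus ebenaui"),
      caa = c(67, 75, 64, 65),
      cag = c(13, 10, 18, 14),
      gaa = c(55, 61, 55, 42),
      gag = c(18, 11, 18, 31),
      total = c(3447, 3436, 3442, 3441)
    )
  )
}

#' Chi-square test for codon-usage deviation from a panel average
#'
#' One-sample goodness-of-fit test (df = 1, no continuity correction): the
#' observed pair of counts is split against the proportion implied by the
#' panel-average counts, under the null hypothesis that the relative
#' frequency is equal from species to species. The three test kinds are
#' CAA vs CAG, GAA vs GAG, and total glutamine (CAA+CAG) vs glutamate
#' (GAA+GAG) codons.
#'
#' @param observed Integer pair of observed counts.
#' @param panel Numeric pair of panel-average counts (both > 0).
#' @param kind One of `"CAA_vs_CAG"`, `"GAA_vs_GAG"`, `"Gln_vs_Glu"`.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `kind`, `observed_1`, `observed_2`,
#'   `expected_1`, `expected_2`, `chi2`, `df`, `p`, `significant`.
#' @export
chisq_deviation <- function(observed, panel,
                            kind = c("CAA_vs_CAG", "GAA_vs_GAG",
                                     "Gln_vs_Glu"),
                            alpha = 0.05) {
  kind <- match.arg(kind)
  if (length(observed) != 2L || length(panel) != 2L) {
    abort("observed and panel must each hold two counts")
  }
  if (sum(observed) <= 0) abort("observed counts sum to zero")
  if (any(panel <= 0)) abort("panel expectation has a zero cell")
  p0 <- panel[1] / sum(panel)
  expected <- sum(observed) * c(p0, 1 - p0)
  chi2 <- sum((observed - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble(kind = kind,
         observed_1 = observed[1], observed_2 = observed[2],
         expected_1 = expected[1], expected_2 = expected[2],
         chi2 = chi2, df = 1L, p = p, significant = p < alpha)
}

#' Codon-usage deviation table for a set of species
#'
#' One row per species with the six glutamine/glutamate codon counts and
#' the three chi-square deviation tests against the panel average;
#' significant cells are marked the way published codon-usage tables
#' asterisk them (CAA/CAG cells for the CAA-vs-CAG test, GAA/GAG for the
#' GAA-vs-GAG test, the two sum columns for the Gln-vs-Glu test).
#'
#' @param species_counts A tibble with columns `species`, `caa`, `cag`,
#'   `gaa`, `gag` (e.g. `gecko_codon_panel()$species`, or [glance()] rows
#'   from [count_codons()]).
#' @param panel A one-row tibble of panel means (`caa`, `cag`, `gaa`,
#'   `gag`), default the 17-gecko panel.
#' @param alpha Significance level.
#' @return A tibble with counts, per-test p-values (`p_caa_cag`,
#'   `p_gaa_gag`, `p_gln_glu`), star logicals (`star_caa_cag`,
#'   `star_gaa_gag`, `star_gln_glu`) and asterisked display cells.
#' @export
usage_table <- function(species_counts, panel = gecko_codon_panel()$panel,
                        alpha = 0.05) {
  if (nrow(species_counts) < 1L) abort("need at least one species")
  rows <- purrr::pmap(species_counts[, c("species", "caa", "cag", "gaa",
                                         "gag")],
    function(species, caa, cag, gaa, gag) {
      t1 <- chisq_deviation(c(caa, cag), c(panel$caa, panel$cag),
                            "CAA_vs_CAG", alpha)
      t2 <- chisq_deviation(c(gaa, gag), c(panel$gaa, panel$gag),
                            "GAA_vs_GAG", alpha)
      t3 <- chisq_deviation(c(caa + cag, gaa + gag),
                            c(panel$caa + panel$cag, panel$gaa + panel$gag),
                            "Gln_vs_Glu", alpha)
      star <- function(x, s) paste0(x, ifelse(s, "*", ""))
      tibble(
        species = species, caa = caa, cag = cag, gln_total = caa + cag,
        gaa = gaa, gag = gag, glu_total = gaa + gag,
        p_caa_cag = t1$p, p_gaa_gag = t2$p, p_gln_glu = t3$p,
        star_caa_cag = t1$significant, star_gaa_gag = t2$significant,
        star_gln_glu = t3$significant,
        cell_caa = star(caa, t1$significant),
        cell_cag = star(cag, t1$significant),
        cell_gaa = star(gaa, t2$significant),
        cell_gag = star(gag, t2$significant),
        cell_gln_total = star(caa + cag, t3$significant),
        cell_glu_total = star(gaa + gag, t3$significant)
      )
    })
  list_rbind(rows)
}
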