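# Shared toy fixtures and independent oracles, built in code.

# Quick pedigree builder from parallel vectors.
mk_ped <- function(id, sire = NA, dam = NA, sex = NA, birth, death = NA) {
  as_pedigree(tibble::tibble(
    id = id,
    sire = rep_len(sire, length(id)),
    dam = rep_len(dam, length(id)),
    sex = rep_len(sex, length(id)),
    birth_year = birth,
    death_year = rep_len(death, length(id))
  ))
}

mk_dip <- function(id, hap1, hap2) {
  tibble::tibble(id = id, hap1 = hap1, hap2 = hap2)
}

# Four-haplotype set with hand-made aligned sequences.
toy_hapset <- function() {
  haplotype_set(
    c("A", "B", "C", "D"),
    c(A = "AAAAAAAAAA", B = "AAAAAAAAAT", C = "TTTTTAAAAA", D = "ACDEFGHIKL")
  )
}

# Exact diplotype distribution for every individual of a toy pedigree under
# the gene-drop rules, by independent recursive enumeration. Assumes the two
# parental lineages of any individual share no common ancestor (true for the
# toy pedigrees used in the tests), so the two transmitted alleles are
# independent and the joint is an outer product.
enum_drop_dist <- function(ped, dips, founder_years, labels) {
  ids <- ped$id
  birth <- setNames(ped$birth_year, ids)
  sire <- setNames(ped$sire, ids)
  dam <- setNames(ped$dam, ids)
  obs1 <- setNames(dips$hap1[match(ids, dips$id)], ids)
  obs2 <- setNames(dips$hap2[match(ids, dips$id)], ids)
  K <- length(labels)

  cohort_freq <- function(y) {
    in_c <- ids[birth == y & !is.na(obs1)]
    if (length(in_c) == 0) return(NULL)
    tab <- table(factor(c(obs1[in_c], obs2[in_c]), levels = labels))
    as.numeric(tab) / sum(tab)
  }
  years_with <- sort(unique(birth[!is.na(obs1)]))
  years_with <- years_with[vapply(years_with,
                                  function(y) !is.null(cohort_freq(y)), logical(1))]
  freq_for_year <- function(y) {
    f <- cohort_freq(y)
    if (!is.null(f)) return(f)
    if (y < founder_years[1]) return(cohort_freq(min(years_with)))
    cand <- years_with[order(abs(years_with - y), years_with)]
    cohort_freq(cand[1])
  }

  joint <- new.env()
  pair <- function(id) {
    if (!is.null(joint[[id]])) return(joint[[id]])
    pre <- birth[[id]] < founder_years[1]
    fw <- birth[[id]] >= founder_years[1] && birth[[id]] <= founder_years[2]
    if ((pre || fw) && !is.na(obs1[[id]])) {
      J <- matrix(0, K, K, dimnames = list(labels, labels))
      J[obs1[[id]], obs2[[id]]] <- 1
    } else if (pre) {
      f <- cohort_freq(min(years_with))
      J <- outer(f, f)
      dimnames(J) <- list(labels, labels)
    } else {
      contrib <- function(parent) {
        if (is.na(parent)) return(freq_for_year(birth[[id]]))
        Jp <- pair(parent)
        (rowSums(Jp) + colSums(Jp)) / 2
      }
      J <- outer(contrib(sire[[id]]), contrib(dam[[id]]))
      dimnames(J) <- list(labels, labels)
    }
    joint[[id]] <- J
    J
  }

  lapply(setNames(ids, ids), function(id) {
    J <- pair(id)
    U <- J + t(J)
    diag(U) <- diag(J)
    U # entries on/above the diagonal are unordered-pair probabilities
  })
}

# Observed unordered-pair frequencies for one individual across replicates of
# a run_genedrop(..., keep_assignments = TRUE) result.
simulated_pair_freqs <- function(drop, id, labels) {
  a <- drop$assignments$hap1[id, ]
  b <- drop$assignments$hap2[id, ]
  key <- paste(pmin(a, b), pmax(a, b), sep = "/")
  all_pairs <- outer(labels, labels, function(x, y) paste(pmin(x, y), pmax(x, y), sep = "/"))
  lev <- unique(all_pairs[upper.tri(all_pairs, diag = TRUE)])
  table(factor(key, levels = lev)) / length(key)
}

# Expected unordered-pair probabilities in the same "min/max" keying.
enum_pair_probs <- function(U, labels) {
  out <- c()
  for (i in seq_along(labels)) {
    for (j in i:length(labels)) {
      out[paste(labels[i], labels[j], sep = "/")] <- U[i, j]
    }
  }
  out
}
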