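# Independent brute-force oracles. These deliberately avoid the package's
# own data structures and algorithms: plain parent-pointer walks, position
# scans and nested loops, so that agreement with the fast implementations is
# meaningful.

library(data.table)

# --- taxonomy -------------------------------------------------------------

ORACLE_RANKS <- c("superkingdom", "phylum", "class", "order",
                  "family", "genus", "species")

# path-walking ancestor lookup on the raw node table
oracle_ancestor <- function(nodes, org, rank) {
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  ranks <- setNames(nodes$rank, nodes$taxon_id)
  names <- setNames(nodes$name, nodes$taxon_id)
  cur <- org
  chain <- character()
  while (cur != "-") {
    chain <- c(chain, cur)
    cur <- parent[[cur]]
  }
  hit <- chain[ranks[chain] == rank]
  if (length(hit)) return(hit[[1]])
  # placeholder: nearest named canonical ancestor shallower than rank
  ri <- match(rank, ORACLE_RANKS)
  anc <- NA_character_
  for (r2 in rev(seq_len(ri - 1L))) {
    cand <- chain[ranks[chain] == ORACLE_RANKS[[r2]]]
    if (length(cand)) {
      anc <- cand[[1]]
      break
    }
  }
  if (is.na(anc)) anc <- chain[[length(chain)]]
  paste0("unclassified:", anc, ":", rank)
}

# subtree scan: organisms whose parent chain passes through any query taxon
oracle_descendants <- function(nodes, organisms, taxa) {
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  hits <- character()
  for (org in organisms) {
    cur <- org
    anc <- character()
    while (cur != "-") {
      anc <- c(anc, cur)
      cur <- parent[[cur]]
    }
    # placeholder ids also count as ancestors
    for (rank in ORACLE_RANKS)
      anc <- c(anc, oracle_ancestor(nodes, org, rank))
    if (any(taxa %in% anc)) hits <- c(hits, org)
  }
  sort(unique(hits))
}

# --- digestion ------------------------------------------------------------

# position-scanning tryptic digest: walk the sequence residue by residue
oracle_digest <- function(seq, max_mc, min_len, max_len) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  is_site <- logical(n)
  for (i in seq_len(n))
    is_site[i] <- ch[i] %in% c("K", "R") && (i == n || ch[i + 1] != "P")
  starts <- c(1L, which(is_site[-n]) + 1L)
  ends <- c(which(is_site[-n]), n)
  out <- character()
  for (a in seq_along(starts)) {
    for (b in a:min(length(ends), a + max_mc)) {
      pep <- paste(ch[starts[a]:ends[b]], collapse = "")
      if (nchar(pep) >= min_len && nchar(pep) <= max_len)
        out <- c(out, pep)
    }
  }
  out
}

# independent monoisotopic residue masses (values as published in standard
# proteomics mass tables, entered separately from the package's table)
ORACLE_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
                 C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
                 H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
                 M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
                 T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

oracle_mass <- function(pep, n_ox = 0) {
  ch <- strsplit(pep, "")[[1]]
  sum(ORACLE_MONO[ch]) + 18.0105646863 +
    57.02146 * sum(ch == "C") + 15.99491 * n_ox
}

# dictionary-based index: per-protein digestion and set union
oracle_index <- function(proteins, max_mc = 2, min_len = 7, max_len = 35,
                         il = TRUE) {
  env <- new.env()
  for (i in seq_len(nrow(proteins))) {
    peps <- oracle_digest(proteins$sequence[i], max_mc, min_len, max_len)
    if (il) peps <- chartr("I", "L", peps)
    for (p in unique(peps))
      assign(p, union(if (exists(p, env)) get(p, env) else character(),
                      proteins$organism_id[i]), envir = env)
  }
  env
}

# brute-force per-rank recount of a profile from raw PSM lists
oracle_profile <- function(psms, nodes, index_pairs, rank, n_spectra) {
  peps <- unique(psms$peptide)
  res <- list()
  pep_orgs <- split(index_pairs$organism_id, index_pairs$peptide)
  pep_n <- table(psms$peptide)
  for (p in peps) {
    taxa <- unique(vapply(pep_orgs[[p]], function(o)
      oracle_ancestor(nodes, o, rank), character(1)))
    for (tx in taxa)
      res[[tx]] <- rbind(res[[tx]],
                         data.frame(peptide = p, n = as.integer(pep_n[[p]]),
                                    specific = length(taxa) == 1L))
  }
  data.table(taxon_id = names(res),
             tsm = vapply(res, function(d) sum(d$n), integer(1)),
             spepep = vapply(res, function(d) sum(d$specific), integer(1)))
}

# --- small fixtures built in code ----------------------------------------

tiny_nodes <- function() {
  data.table(
    taxon_id = c("root", "p1", "c1", "o1", "f1", "f2", "g1", "g2", "g3",
                 "s1", "s2", "s3", "s4"),
    name = c("Bacteria", "Phy", "Cla", "Ord", "FamA", "FamB",
             "GenA1", "GenA2", "GenB1",
             "SpA1a", "SpA1b", "SpA2a", "SpB1a"),
    rank = c("superkingdom", "phylum", "class", "order", "family", "family",
             "genus", "genus", "genus",
             "species", "species", "species", "species"),
    parent_id = c("-", "root", "p1", "c1", "o1", "o1", "f1", "f1", "f2",
                  "g1", "g1", "g2", "g3"))
}

tiny_tree <- function() taxonomy_tree(tiny_nodes())

random_protein_seq <- function(len) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
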