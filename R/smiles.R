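# SMILES export.
#
# The writer walks the atomic graph depth-first in atom order (stable under
# a fixed seed), emits lowercase aromatic atoms, '=' for the side-chain
# double bond, an explicit '-' for non-aromatic bonds between two aromatic
# atoms (the 5-5 biphenyl bond), and ring-closure digits (with reuse, %nn
# beyond 9) for every cycle.  Assembly is iterative (reverse preorder), so
# arbitrarily large polymers do not recurse.

#' Export a polymer as a SMILES string
#'
#' @param p A valid `lignin_polymer`.
#' @return A single SMILES string; parsing it back yields a molecule with
#'   the same heavy-atom formula, with aromatic rings encoded aromatically.
#' @export
to_smiles <- function(p) {
  .check_polymer(p)
  n <- length(p$a_mono)
  if (n == 0L) .abort("cannot export an empty polymer")
  viol <- validate_polymer(p)
  if (length(viol)) {
    .abort(paste("invalid structure:", viol[1]), "ligninsim_corrupt")
  }
  nb <- vector("list", n)
  border <- p$b_order; barom <- p$b_arom
  for (k in seq_along(p$b_i)) {
    i <- p$b_i[k]; j <- p$b_j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, sort)
  bond_key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  binfo <- new.env(parent = emptyenv())
  for (k in seq_along(p$b_i)) {
    assign(bond_key(p$b_i[k], p$b_j[k]), c(border[k], barom[k]), envir = binfo)
  }
  bond_sym <- function(i, j) {
    b <- get(bond_key(i, j), envir = binfo)
    if (b[2] == 1) "" # aromatic ring bond
    else if (b[1] == 2) "="
    else if (p$a_arom[i] && p$a_arom[j]) "-" # single bond between aromatic atoms
    else ""
  }
  # iterative DFS: preorder, parent, children; non-tree edges become ring
  # closures opened at the earlier endpoint
  parent <- integer(n); order <- integer(n); children <- vector("list", n)
  visited <- logical(n)
  back_first <- vector("list", n); back_second <- vector("list", n)
  stack <- 1L; parent[1L] <- 0L; cnt <- 0L
  pre <- integer(n)
  while (length(stack)) {
    a <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (visited[a]) next
    visited[a] <- TRUE
    cnt <- cnt + 1L; pre[a] <- cnt; order[cnt] <- a
    for (v in rev(nb[[a]])) {
      if (!visited[v]) {
        parent[v] <- a
        stack <- c(stack, v)
      }
    }
  }
  # classify edges now that preorder is known
  for (k in seq_along(p$b_i)) {
    i <- p$b_i[k]; j <- p$b_j[k]
    if (parent[i] == j || parent[j] == i) next
    u <- if (pre[i] < pre[j]) i else j
    v <- if (pre[i] < pre[j]) j else i
    back_first[[u]] <- c(back_first[[u]], v)
    back_second[[v]] <- c(back_second[[v]], u)
  }
  # children in DFS-tree order (by preorder)
  for (a in seq_len(n)) {
    if (parent[a] > 0L) children[[parent[a]]] <- c(children[[parent[a]]], a)
  }
  children <- lapply(children, function(ch) ch[base::order(pre[ch])])
  # ring-closure digits with reuse
  pool <- seq_len(99L)
  digit_of <- new.env(parent = emptyenv())
  ring_tok <- vector("character", n)
  fmt_digit <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)
  for (idx in seq_len(cnt)) {
    a <- order[idx]
    toks <- character(0)
    for (v in back_second[[a]]) { # closing occurrences first
      d <- get(bond_key(a, v), envir = digit_of)
      pool <- sort(c(pool, d))
      toks <- c(toks, paste0(bond_sym(a, v), fmt_digit(d)))
    }
    for (v in back_first[[a]]) { # opening occurrences
      d <- pool[1L]; pool <- pool[-1L]
      assign(bond_key(a, v), d, envir = digit_of)
      toks <- c(toks, paste0(bond_sym(a, v), fmt_digit(d)))
    }
    ring_tok[a] <- paste(toks, collapse = "")
  }
  atom_tok <- ifelse(p$a_elem == "O", "O", ifelse(p$a_arom, "c", "C"))
  # assemble fragments in reverse preorder so children resolve first
  frag <- character(n)
  for (idx in rev(seq_len(cnt))) {
    a <- order[idx]
    s <- paste0(atom_tok[a], ring_tok[a])
    ch <- children[[a]]
    if (length(ch)) {
      parts <- vapply(ch, function(v) paste0(bond_sym(a, v), frag[v]), character(1))
      if (length(parts) > 1L) {
        parts <- c(paste0("(", parts[-length(parts)], ")"), parts[length(parts)])
      }
      s <- paste0(s, paste(parts, collapse = ""))
    }
    frag[a] <- s
  }
  frag[order[1L]]
}

#' Heavy-atom and implicit-hydrogen formula of a polymer
#'
#' @param p A `lignin_polymer`.
#' @return Named integer vector with counts of `C`, `H` and `O`.
#' @export
polymer_formula <- function(p) {
  .check_polymer(p)
  n <- length(p$a_mono)
  osum <- numeric(n)
  for (k in seq_along(p$b_i)) {
    osum[p$b_i[k]] <- osum[p$b_i[k]] + p$b_order[k]
    osum[p$b_j[k]] <- osum[p$b_j[k]] + p$b_order[k]
  }
  vmax <- ifelse(p$a_elem == "C", 4, 2)
  c(C = sum(p$a_elem == "C"),
    H = as.integer(sum(pmax(vmax - osum, 0))),
    O = sum(p$a_elem == "O"))
}
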