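# Fast assembly of the transposed Jacobian of the semi-discrete right-hand
# side. Every RHS term we linearize has the frozen-coefficient form
#   contribution_to_state[s_out] = a(x, t) * (D u[s_in])
# with a fixed sparse stencil matrix D (possibly identity) and a node-wise
# coefficient field a. Its transpose contributes triplets
#   JT[(s_in, col(D)), (s_out, row(D))] = D_x * a[row(D)]
# with a fixed sparsity pattern, so the whole transposed Jacobian can be
# reassembled each backward step by rescaling one precomputed triplet list.

# part: list(D = sparse n x n base matrix or NULL (node-diagonal),
#            s_in =, s_out =, coef = function(ctx) length-n field)
make_jt_assembler <- function(parts, n, ns, interleave) {
  ndof <- n * ns
  if (!length(parts)) {
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(ndof, ndof))
    return(function(ctx) Z)
  }
  idx <- function(node, state) {
    if (interleave) (node - 1L) * ns + state else (state - 1L) * n + node
  }
  rows <- list(); cols <- list(); xb <- list(); amap <- list()
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (is.null(p$D)) {
      rows[[k]] <- idx(seq_len(n), p$s_in)
      cols[[k]] <- idx(seq_len(n), p$s_out)
      xb[[k]] <- rep(1, n)
      amap[[k]] <- seq_len(n)
    } else {
      Dt <- methods::as(methods::as(p$D, "generalMatrix"), "TsparseMatrix")
      i0 <- Dt@i + 1L   # original rows
      j0 <- Dt@j + 1L   # original cols
      rows[[k]] <- idx(j0, p$s_in)
      cols[[k]] <- idx(i0, p$s_out)
      xb[[k]] <- Dt@x
      amap[[k]] <- i0
    }
  }
  all_rows <- unlist(rows); all_cols <- unlist(cols)
  xbase <- unlist(xb)
  lens <- vapply(xb, length, integer(1))
  offs <- cumsum(c(0L, lens))
  coefs <- lapply(parts, `[[`, "coef")
  # fixed sparsity: prebuild the CSC template once, then refresh only the
  # value slot (duplicate triplets are collapsed in column-major order)
  template <- Matrix::sparseMatrix(i = all_rows, j = all_cols, x = xbase,
                                   dims = c(ndof, ndof))
  ord <- order(all_cols, all_rows)
  ro <- all_rows[ord]; co <- all_cols[ord]
  grp <- cumsum(c(TRUE, diff(co) != 0L | diff(ro) != 0L))
  if (max(grp) != length(template@x)) stop("sparsity bookkeeping mismatch")
  function(ctx) {
    xx <- xbase
    for (k in seq_along(coefs)) {
      a <- coefs[[k]](ctx)
      rng <- (offs[k] + 1L):offs[k + 1L]
      xx[rng] <- xx[rng] * a[amap[[k]]]
    }
    A <- template
    A@x <- as.numeric(rowsum(xx[ord], grp, reorder = FALSE))
    A
  }
}

# transposed-Jacobian parts of a linear library closure
linear_closure_jt_parts <- function(cl, sys) {
  parts <- list()
  for (k in seq_along(cl$lib$terms)) {
    for (g in cl$lib$terms[[k]]$grads) {
      for (s_out in seq_len(cl$n_states)) {
        local({
          k_ <- k; g_ <- g; s_out_ <- s_out
          D <- if (g_$order == 0L) NULL else sys$free_ops[[g_$order]]$D
          parts[[length(parts) + 1L]] <<- list(
            D = D, s_in = g_$state, s_out = s_out_,
            coef = function(ctx) {
              aw <- sum(cl$A[s_out_, ] * cl$W[k_, ])
              if (aw == 0) numeric(ctx$n) else aw * g_$fn(ctx$env)
            })
        })
      }
    }
  }
  parts
}
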