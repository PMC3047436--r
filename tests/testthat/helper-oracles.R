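# Independent oracles: direct hand transcriptions of the 25 flux laws, the
# 9 balance equations and their analytic state-Jacobian, written without
# reference to the package's stoichiometry/design machinery.

oracle_rhs <- function(state, inputs, p) {
  x <- as.list(state); u <- as.list(inputs); p <- as.list(p)
  with(c(x, u, p), {
    v1  <- kf1 * DHSph * CoA16 * CerS6
    v2  <- kf2 * DHSph * CoA16
    v3  <- kf3 * C16DHCer
    v4  <- kf4 * DHSph * Sphk1
    v5  <- kf5 * DHSph * Sphk2
    v6  <- kf6 * DHSph1P
    v7  <- kf7 * C16DHCer * Ugcg
    v8  <- kf8 * C16DHGlcCer
    v9  <- kf9 * C16DHCer * Sms1 * C16GPCho - kb9 * C16DHSM * Sms1 * C16DG
    v10 <- kf10 * C16DHCer * Sms2 * C16GPCho - kb10 * C16DHSM * Sms2 * C16DG
    v11 <- kf11 * C16DHSM * Smpd1
    v12 <- kf12 * C16DHSM
    v13 <- kf13 * C16DHCer * Cerk
    v14 <- kf14 * C16DHCerP
    v15 <- kf15 * C16DHCer * Degs1
    v16 <- kf16 * C16DHCer
    v17 <- kf17 * C16Cer * Cerk
    v18 <- kf18 * C16CerP
    v19 <- kf19 * C16Cer * Sms1 * C16GPCho - kb19 * C16SM * Sms1 * C16DG
    v20 <- kf20 * C16Cer * Sms2 * C16GPCho - kb20 * C16SM * Sms2 * C16DG
    v21 <- kf21 * C16SM * Smpd1
    v22 <- kf22 * C16SM
    v23 <- kf23 * C16Cer
    v24 <- kf24 * C16Cer * Ugcg
    v25 <- kf25 * C16GlcCer
    c(C16DHCer = v1 + v2 - v3 - v7 - v9 - v10 + v11 - v13 - v15 - v16,
      DHSph1P = v4 + v5 - v6,
      C16DHGlcCer = v7 - v8,
      C16DHSM = v9 + v10 - v11 - v12,
      C16DHCerP = v13 - v14,
      C16Cer = v15 + v16 - v17 - v19 - v20 + v21 - v23 - v24,
      C16CerP = v17 - v18,
      C16SM = v19 + v20 - v21 - v22,
      C16GlcCer = v24 - v25)
  })
}

oracle_jacobian <- function(inputs, p) {
  u <- as.list(inputs); p <- as.list(p)
  with(c(u, p), {
    J <- matrix(0, 9, 9)
    J[1, 1] <- -(kf3 + kf7 * Ugcg + kf9 * Sms1 * C16GPCho +
                   kf10 * Sms2 * C16GPCho + kf13 * Cerk + kf15 * Degs1 + kf16)
    J[1, 4] <- kb9 * Sms1 * C16DG + kb10 * Sms2 * C16DG + kf11 * Smpd1
    J[2, 2] <- -kf6
    J[3, 1] <- kf7 * Ugcg
    J[3, 3] <- -kf8
    J[4, 1] <- kf9 * Sms1 * C16GPCho + kf10 * Sms2 * C16GPCho
    J[4, 4] <- -(kb9 * Sms1 * C16DG + kb10 * Sms2 * C16DG +
                   kf11 * Smpd1 + kf12)
    J[5, 1] <- kf13 * Cerk
    J[5, 5] <- -kf14
    J[6, 1] <- kf15 * Degs1 + kf16
    J[6, 6] <- -(kf17 * Cerk + kf19 * Sms1 * C16GPCho +
                   kf20 * Sms2 * C16GPCho + kf23 + kf24 * Ugcg)
    J[6, 8] <- kb19 * Sms1 * C16DG + kb20 * Sms2 * C16DG + kf21 * Smpd1
    J[7, 6] <- kf17 * Cerk
    J[7, 7] <- -kf18
    J[8, 6] <- kf19 * Sms1 * C16GPCho + kf20 * Sms2 * C16GPCho
    J[8, 8] <- -(kb19 * Sms1 * C16DG + kb20 * Sms2 * C16DG +
                   kf21 * Smpd1 + kf22)
    J[9, 6] <- kf24 * Ugcg
    J[9, 9] <- -kf25
    J
  })
}

# random nonnegative states/inputs/params on scales spanning the data range
rand_state <- function() stats::setNames(stats::runif(9, 0, 10) *
                                           10^sample(-2:2, 9, TRUE),
                                         NET$dynamic)
rand_inputs <- function() stats::setNames(stats::runif(13, 0, 3), NET$inputs)
rand_params <- function() stats::setNames(stats::runif(29, 0, 2),
                                          NET$param_names)
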