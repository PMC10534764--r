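#include <R.h>
#include <Rinternals.h>

/* 3D convolution kernels over 5-D column-major arrays (H, W, T, B, C).
 * The R side pads the input; here we run a "valid" convolution:
 *   y[h,w,t,b,co] = bias[co] +
 *     sum_{i,j,l,ci} xp[h+i, w+j, t+l, b, ci] * Wt[i,j,l,ci,co]
 */

static R_INLINE const int *dims_of(SEXP x)
{
    return INTEGER(getAttrib(x, R_DimSymbol));
}

SEXP C_conv3_fwd(SEXP xpS, SEXP wS, SEXP bS)
{
    const double *xp = REAL(xpS), *W = REAL(wS), *bias = REAL(bS);
    const int *dx = dims_of(xpS);   /* Hp, Wp, Tp, B, Cin */
    const int *dw = dims_of(wS);    /* kh, kw, kt, Cin, Cout */
    const int Hp = dx[0], Wp = dx[1], Tp = dx[2], B = dx[3], Cin = dx[4];
    const int kh = dw[0], kw = dw[1], kt = dw[2], Cout = dw[4];
    const int H = Hp - kh + 1, Wd = Wp - kw + 1, T = Tp - kt + 1;
    SEXP yS = PROTECT(allocVector(REALSXP, (R_xlen_t) H * Wd * T * B * Cout));
    SEXP dimS = PROTECT(allocVector(INTSXP, 5));
    INTEGER(dimS)[0] = H; INTEGER(dimS)[1] = Wd; INTEGER(dimS)[2] = T;
    INTEGER(dimS)[3] = B; INTEGER(dimS)[4] = Cout;
    setAttrib(yS, R_DimSymbol, dimS);
    double *y = REAL(yS);
    const R_xlen_t nSlab = (R_xlen_t) H * Wd * T * B;

    for (int co = 0; co < Cout; co++) {
        double *yc = y + nSlab * co;
        const double bco = bias[co];
        for (R_xlen_t p = 0; p < nSlab; p++) yc[p] = bco;
        for (int ci = 0; ci < Cin; ci++) {
            const double *xc = xp + (R_xlen_t) Hp * Wp * Tp * B * ci;
            for (int l = 0; l < kt; l++)
            for (int j = 0; j < kw; j++)
            for (int i = 0; i < kh; i++) {
                const double wv =
                    W[i + kh * (j + kw * (l + kt * (ci + (R_xlen_t) Cin * co)))];
                if (wv == 0.0) continue;
                for (int b = 0; b < B; b++)
                for (int t = 0; t < T; t++)
                for (int w = 0; w < Wd; w++) {
                    const double *xrow = xc +
                        (R_xlen_t) i + Hp * ((w + j) + (R_xlen_t) Wp *
                            ((t + l) + (R_xlen_t) Tp * b));
                    double *yrow = yc +
                        Hp * 0 + (R_xlen_t) H * (w + (R_xlen_t) Wd *
                            (t + (R_xlen_t) T * b));
                    for (int h = 0; h < H; h++)
                        yrow[h] += wv * xrow[h];
                }
            }
        }
    }
    UNPROTECT(2);
    return yS;
}

/* backward: given padded input xp and output gradient dy, produce
 * dxp (same shape as xp) and dW (same shape as W). db is colSums in R. */
SEXP C_conv3_bwd(SEXP xpS, SEXP dyS, SEXP wS)
{
    const double *xp = REAL(xpS), *dy = REAL(dyS), *W = REAL(wS);
    const int *dx = dims_of(xpS);
    const int *dw = dims_of(wS);
    const int *dd = dims_of(dyS);
    const int Hp = dx[0], Wp = dx[1], Tp = dx[2], B = dx[3], Cin = dx[4];
    const int kh = dw[0], kw = dw[1], kt = dw[2], Cout = dw[4];
    const int H = dd[0], Wd = dd[1], T = dd[2];
    SEXP dxpS = PROTECT(allocVector(REALSXP, XLENGTH(xpS)));
    setAttrib(dxpS, R_DimSymbol, getAttrib(xpS, R_DimSymbol));
    SEXP dWS = PROTECT(allocVector(REALSXP, XLENGTH(wS)));
    setAttrib(dWS, R_DimSymbol, getAttrib(wS, R_DimSymbol));
    double *dxp = REAL(dxpS), *dWv = REAL(dWS);
    memset(dxp, 0, XLENGTH(xpS) * sizeof(double));
    memset(dWv, 0, XLENGTH(wS) * sizeof(double));
    const R_xlen_t nSlab = (R_xlen_t) H * Wd * T * B;

    for (int co = 0; co < Cout; co++) {
        const double *dyc = dy + nSlab * co;
        for (int ci = 0; ci < Cin; ci++) {
            const double *xc = xp + (R_xlen_t) Hp * Wp * Tp * B * ci;
            double *dxc = dxp + (R_xlen_t) Hp * Wp * Tp * B * ci;
            for (int l = 0; l < kt; l++)
            for (int j = 0; j < kw; j++)
            for (int i = 0; i < kh; i++) {
                const R_xlen_t widx =
                    i + kh * (j + kw * (l + kt * (ci + (R_xlen_t) Cin * co)));
                const double wv = W[widx];
                double acc = 0.0;
                for (int b = 0; b < B; b++)
                for (int t = 0; t < T; t++)
                for (int w = 0; w < Wd; w++) {
                    const R_xlen_t xoff =
                        (R_xlen_t) i + Hp * ((w + j) + (R_xlen_t) Wp *
                            ((t + l) + (R_xlen_t) Tp * b));
                    const R_xlen_t yoff =
                        (R_xlen_t) H * (w + (R_xlen_t) Wd *
                            (t + (R_xlen_t) T * b));
                    const double *xrow = xc + xoff;
                    double *dxrow = dxc + xoff;
                    const double *dyrow = dyc + yoff;
                    for (int h = 0; h < H; h++) {
                        acc += dyrow[h] * xrow[h];
                        dxrow[h] += wv * dyrow[h];
                    }
                }
                dWv[widx] = acc;
            }
        }
    }
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dxpS);
    SET_VECTOR_ELT(out, 1, dWS);
    UNPROTECT(3);
    return out;
}

/* ceil-mode 3D max pooling; returns list(y, win) where win holds 1-based
 * linear indices into x of each maximum (0 when the window was empty,
 * which cannot happen with ceil mode). */
SEXP C_pool3_fwd(SEXP xS, SEXP pS)
{
    const double *x = REAL(xS);
    const int *dx = dims_of(xS);
    const int *p = INTEGER(pS);
    const int H = dx[0], W = dx[1], T = dx[2], B = dx[3], C = dx[4];
    const int ph = p[0], pw = p[1], pt = p[2];
    const int Ho = (H + ph - 1) / ph, Wo = (W + pw - 1) / pw,
              To = (T + pt - 1) / pt;
    R_xlen_t n = (R_xlen_t) Ho * Wo * To * B * C;
    SEXP yS = PROTECT(allocVector(REALSXP, n));
    SEXP winS = PROTECT(allocVector(REALSXP, n));
    SEXP dimS = PROTECT(allocVector(INTSXP, 5));
    INTEGER(dimS)[0] = Ho; INTEGER(dimS)[1] = Wo; INTEGER(dimS)[2] = To;
    INTEGER(dimS)[3] = B; INTEGER(dimS)[4] = C;
    setAttrib(yS, R_DimSymbol, dimS);
    double *y = REAL(yS), *win = REAL(winS);
    R_xlen_t o = 0;
    for (int c = 0; c < C; c++)
    for (int b = 0; b < B; b++)
    for (int to = 0; to < To; to++)
    for (int wo = 0; wo < Wo; wo++)
    for (int ho = 0; ho < Ho; ho++) {
        double best = R_NegInf;
        R_xlen_t bi = 0;
        for (int l = to * pt; l < (to + 1) * pt && l < T; l++)
        for (int j = wo * pw; j < (wo + 1) * pw && j < W; j++)
        for (int i = ho * ph; i < (ho + 1) * ph && i < H; i++) {
            R_xlen_t xi = i + (R_xlen_t) H * (j + (R_xlen_t) W *
                (l + (R_xlen_t) T * (b + (R_xlen_t) B * c)));
            if (x[xi] > best) { best = x[xi]; bi = xi + 1; }
        }
        /* output is laid out (Ho, Wo, To, B, C) but we iterate ho fastest
         * within (c, b, to, wo): compute the index explicitly */
        R_xlen_t yi = ho + (R_xlen_t) Ho * (wo + (R_xlen_t) Wo *
            (to + (R_xlen_t) To * (b + (R_xlen_t) B * c)));
        y[yi] = best;
        win[yi] = (double) bi;
        o++;
    }
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, yS);
    SET_VECTOR_ELT(out, 1, winS);
    UNPROTECT(4);
    return out;
}

SEXP C_pool3_bwd(SEXP winS, SEXP dyS, SEXP nS)
{
    const double *win = REAL(winS), *dy = REAL(dyS);
    R_xlen_t n = (R_xlen_t) REAL(nS)[0];
    SEXP dxS = PROTECT(allocVector(REALSXP, n));
    double *dxv = REAL(dxS);
    memset(dxv, 0, n * sizeof(double));
    R_xlen_t m = XLENGTH(dyS);
    for (R_xlen_t i = 0; i < m; i++) {
        R_xlen_t w = (R_xlen_t) win[i];
        if (w > 0) dxv[w - 1] += dy[i];
    }
    UNPROTECT(1);
    return dxS;
}

/* rasterize capsule splats into a depth image (row-major: H x W matrix,
 * column-major storage). pts is an n x 4 matrix: u (col), v (row), pixel
 * radius, surface depth value. Each pixel keeps the nearest surface. */
SEXP C_splat(SEXP depthS, SEXP ptsS)
{
    SEXP outS = PROTECT(duplicate(depthS));
    double *d = REAL(outS);
    const double *p = REAL(ptsS);
    const int *dd = dims_of(depthS);
    const int H = dd[0], W = dd[1];
    const int n = dims_of(ptsS)[0];
    for (int k = 0; k < n; k++) {
        const double u = p[k], v = p[k + n], pr = p[k + 2 * n],
                     val = p[k + 3 * n];
        int c0 = (int) floor(u - pr), c1 = (int) ceil(u + pr);
        int r0 = (int) floor(v - pr), r1 = (int) ceil(v + pr);
        if (c0 < 1) c0 = 1; if (c1 > W) c1 = W;
        if (r0 < 1) r0 = 1; if (r1 > H) r1 = H;
        const double pr2 = pr * pr;
        for (int c = c0; c <= c1; c++) {
            const double dc2 = (c - u) * (c - u);
            double *col = d + (R_xlen_t) H * (c - 1);
            for (int r = r0; r <= r1; r++) {
                const double d2 = dc2 + (r - v) * (r - v);
                if (d2 <= pr2 && col[r - 1] > val) col[r - 1] = val;
            }
        }
    }
    UNPROTECT(1);
    return outS;
}
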