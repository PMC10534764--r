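#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* CRC-32 (IEEE 802.3 / PNG polynomial), table-driven. */

static unsigned int crc_table[256];
static int crc_table_ready = 0;

static void make_crc_table(void)
{
    unsigned int c;
    int n, k;
    for (n = 0; n < 256; n++) {
        c = (unsigned int) n;
        for (k = 0; k < 8; k++)
            c = (c & 1) ? 0xedb88320U ^ (c >> 1) : c >> 1;
        crc_table[n] = c;
    }
    crc_table_ready = 1;
}

SEXP C_crc32(SEXP data)
{
    const unsigned char *p = RAW(data);
    R_xlen_t n = XLENGTH(data), i;
    unsigned int c = 0xffffffffU;
    if (!crc_table_ready) make_crc_table();
    for (i = 0; i < n; i++)
        c = crc_table[(c ^ p[i]) & 0xff] ^ (c >> 8);
    return ScalarReal((double) (c ^ 0xffffffffU));
}

SEXP C_conv3_fwd(SEXP xpS, SEXP wS, SEXP bS);
SEXP C_conv3_bwd(SEXP xpS, SEXP dyS, SEXP wS);
SEXP C_pool3_fwd(SEXP xS, SEXP pS);
SEXP C_pool3_bwd(SEXP winS, SEXP dyS, SEXP nS);
SEXP C_splat(SEXP depthS, SEXP ptsS);

static const R_CallMethodDef callMethods[] = {
    {"C_crc32", (DL_FUNC) &C_crc32, 1},
    {"C_conv3_fwd", (DL_FUNC) &C_conv3_fwd, 3},
    {"C_conv3_bwd", (DL_FUNC) &C_conv3_bwd, 3},
    {"C_pool3_fwd", (DL_FUNC) &C_pool3_fwd, 2},
    {"C_pool3_bwd", (DL_FUNC) &C_pool3_bwd, 3},
    {"C_splat", (DL_FUNC) &C_splat, 2},
    {NULL, NULL, 0}
};

void R_init_DepthTAL(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
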