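/* Compiled right-hand side of the whole-body arsenic model for deSolve.
 *
 * State order (15): gut, gut_MMA, gut_DMA, BiAs, BMMAs, BDMAs, bodystore,
 * LiAs, LiAs_store, LMMAs, LDMAs, LDMAs_store, UiAs, UMMAs, UDMAs.
 * Parameter vector order must match rhs_parms_vector() on the R side.
 */
#include <R.h>

static double parms[32];

#define K1I  parms[0]
#define K1M  parms[1]
#define K1D  parms[2]
#define K2   parms[3]
#define KM2  parms[4]
#define K3   parms[5]
#define KM3  parms[6]
#define K4   parms[7]
#define KM4  parms[8]
#define K5   parms[9]
#define KM5  parms[10]
#define K6   parms[11]
#define K7   parms[12]
#define K8   parms[13]
#define K9   parms[14]
#define KM9  parms[15]
#define K10  parms[16]
#define KM10 parms[17]
#define RGB  parms[18]
#define RLB  parms[19]
#define RSB  parms[20]
#define VOLB parms[21]
#define VM1  parms[22]
#define VM2  parms[23]
#define KMM1 parms[24]
#define KMM2 parms[25]
#define KSI  parms[26]
#define KIP  parms[27]
#define KII  parms[28]
#define INI  parms[29]
#define INM  parms[30]
#define IND  parms[31]

void asmethyl_initmod(void (*odeparms)(int *, double *)) {
  int n = 32;
  odeparms(&n, parms);
}

void asmethyl_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  double LiAs = y[7] > 0 ? y[7] : 0;
  double LMMA = y[9] > 0 ? y[9] : 0;
  double V1 = VM1 * LiAs /
    ((KMM1 + LiAs) * (1 + LiAs / KSI) * (1 + LMMA / KIP));
  double V2 = VM2 * LMMA / ((KMM2 + LMMA) * (1 + LiAs / KII));

  ydot[0] = INI - K1I * y[0];
  ydot[1] = INM - K1M * y[1];
  ydot[2] = IND - K1D * y[2];
  ydot[3] = K1I * RGB * y[0] + KM2 * RSB * y[6] + KM3 * RLB * y[7] -
            (K3 + K2 + K6) * y[3];
  ydot[4] = K1M * RGB * y[1] + KM4 * RLB * y[9] - (K4 + K7) * y[4];
  ydot[5] = K1D * RGB * y[2] + KM5 * RLB * y[10] - (K5 + K8) * y[5];
  ydot[6] = K2 / RSB * y[3] - KM2 * y[6];
  ydot[7] = K3 / RLB * y[3] - KM3 * y[7] + KM9 * y[8] - K9 * y[7] - V1;
  ydot[8] = K9 * y[7] - KM9 * y[8];
  ydot[9] = K4 / RLB * y[4] - KM4 * y[9] + V1 - V2;
  ydot[10] = K5 / RLB * y[5] - KM5 * y[10] + V2 + KM10 * y[11] - K10 * y[10];
  ydot[11] = K10 * y[10] - KM10 * y[11];
  ydot[12] = VOLB * K6 * y[3];
  ydot[13] = VOLB * K7 * y[4];
  ydot[14] = VOLB * K8 * y[5];
}
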