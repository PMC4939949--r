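HMMER3/f [toy fixture]
NAME  toy2
DESC  two-state toy model
LENG  2
ALPH  amino
HMM                 A        C        D        E        F        G        H        I        K        L        M        N        P        Q        R        S        T        V        W        Y
                m->m     m->i     m->d     i->m     i->i     d->m     d->d
  COMPO    2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573
           2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573
           0.10536  2.99573  2.99573  0.35667  1.20397  0.10536  2.30259
      1    0.22314  1.60944        *        *        *        *        *        *        *        *        *        *        *        *        *        *        *        *        *        *
           2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573
           0.10536  2.99573  2.99573  0.35667  1.20397  0.10536  2.30259
      2          *        *        *        *        *  0.35667  1.20397        *        *        *        *        *        *        *        *        *        *        *        *        *
           2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573  2.99573
           0.05129  2.99573        *  0.35667  1.20397 -0.00000        *
//
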