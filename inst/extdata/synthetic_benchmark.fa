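>dF01S01m01 x.1.1.1
FPWGMTSEYLCNPFPHLGAQEPRDNDVYTMPPEKIGNTSEHRPYAIPDRVCFTFTTLDVP
NLVKWNAAVLQWFHYHEHKGWT
>dF01S01m02 x.1.1.1
FAVGPTQEYLCNPFPDLEPQEPRWTEDYTMPPAYGGNTSEHRPYIIALRVGMTFITLQEP
MPVKARAICLQWFHKFAHKGQF
>dF01S01m03 x.1.1.1
FKVDGTSYYNCNPFPEDGAQKCIWNWHQMMPPEYDGNTEEHRPYISKDRVPRTFIRLDEP
NPVKIIAICFQWFKPHAVKGPF
>dF01S02m01 x.1.2.1
KGKTTSCQMAHKTDKNHMFWFAIRYNFAAGDCNRLEFKTVDCTHDWDDMLGKSSAGQNLT
QEDTWQACTVPRQRVV
>dF01S02m02 x.1.2.1
NGKWTSDGNALKARKLHWFPFAIRWDFAAARCNRLTYKAVDCIHDTQDNLMKDSAMWNPP
QEQTWPELTVPRDNKY
>dF01S02m03 x.1.2.1
FGKTTSNGYALKADKLHSFWGFIKWNFAEGFCNWLQYKANFCIHDTDDMMMKSSAGWNLS
HVAGEPELINPRDNFY
>dF02S01m01 x.2.1.1
IQDPYQPMMFPYTKRDRVSCVPYRWMCMFLIMRHHGHGALFRAWALRELYEAHVAEAGST
AHETAARSEG
>dF02S01m02 x.2.1.1
LQTGYQPMMFPYDTDDYSSRWPYHWICMFRYMNHHGHHAPFDGWHLCKYYDQLVAEAHVY
AFHEAAHGEG
>dF02S01m03 x.2.1.1
LPDPYQQVNIPYTERDYNSCWPTTWMCMFNYMQHHGHGKSFRKWHLRPSDAWHVAEAWVY
EFKFAAQGEG
>dF02S02m01 x.2.2.1
HFAGSYIVWRINKMYIHAVSKEMAVGHPKECFACGKRCNKPPLDRPWFDDMPHLCIQQRT
DSGQRNRCGSFITPGLGPLNKEGIPDQKDDTQVA
>dF02S02m02 x.2.2.1
PFSGSYIVTCINKEYIHDSSKHMKVNFRKLCSMCGRRCNKLPQDDPNFDDVYNHSIPQWC
VVGNRNRCGPFNIPGVRPLMKEDIRDIWYDTQFA
>dF02S02m03 x.2.2.1
PEAGSYHVYCIYKEFLFDYSKEMAVQERKECFKCENRANKPPDDDPNWHDVAYRMIQGRC
NDFNRNYAGTFNIPGPCPLNVETIFDQWDYTMFA
>dF03S01m01 x.3.1.1
KIMGYRYHIFWKHYDPEPNDSFFNEWNCNEVWSDQLLWESIKTCSHLQHGCCATEDLYNK
QDKANNHNEIQTAKWYFHKKWPNIDTEWLPQRE
>dF03S01m02 x.3.1.1
KSYGYRTNPVIKHATPEFNHSFINNWNCNWVWSSQLDKKNTDTDMHLMKGGCQTFAPYWI
QTTAINHDSIRTPAIYRRKLHYYIDTVWLDRRE
>dF03S01m03 x.3.1.1
KQYGGMTWFPVKAATPDVNWSWFNYWMCCMVDSDQLLKKSIDTCSDLWHGGHRSFDPVNC
QGILISHNEILTYPFVAWKLEYYNDTVWLDQRW
>dF03S02m01 x.3.2.1
VYHCALSSYEFCTINAPQSPHPRLSCRWVVWCTDEPPSRGNCGGWNYDMCKKSSARTLTC
WDLSCERKNEQLVSDSINQGHMWDFMPASITISPWE
>dF03S02m02 x.3.2.1
VMHYRVSSYPFCVWNAPVHPCWDLSPFYVVMFFDEPPPRKANMGHMYDMHEKSDTRCLYC
WVKSHDDKNNELPSNSINQGHVWGFMAQQTTLNQWK
>dF03S02m03 x.3.2.1
VMHRRLGSHPPCVKSAPISPQYDWKWRWVWWFFDEPPPVKAEGGWNNWMADKSCTRTMYD
WEKSHWHGNNQKPSTSQNQGHVWLFMIAQTTDSQWK
>dF04S01m01 x.4.1.1
PKWFEHDWYHYKPFVHQVTKIFIFHFHWKNVTHLGPGITDARHWEIDKQKQYGWWMITDK
IMINDCKNVRPERGRRARDIAHSWAADIYH
>dF04S01m02 x.4.1.1
PDWCEHDNFHYVPYVAAYTAQCGFHNAYKHVLRLVNCITDLRPWALDFQKQYWWYMNTDI
ICINDHKGVYIWSGRGAPDWPFKWAGDIPC
>dF04S01m03 x.4.1.1
THSCEHAIAHYVPYGAAYNYQGVFHAFWKNVLFLGQCITDMRRWEIQKQKFWMWQMCCDA
IWSNDVKNNYIASGSGAPDSTCSWRADWPW
>dF04S02m01 x.4.2.1
GHEQIMIRTVNHKVRQAIQPPWWQVCWTGWMEEEFHSVSPNVVDDGGSYYWGEANMERFR
EFDVKNIPGVDQCCDWDWDSCEEIAVI
>dF04S02m02 x.4.2.1
GCERITIHKDHKKWRQAIEIPQWMDCPKVWGPEEFKPVHKNVYVDGMSYIVGYLCMEPDH
EFDEKGPVGVDYCLDWDWESMEYCWIT
>dF04S02m03 x.4.2.1
GRTMWMISGANHKQRQAIPPPCAMNCIKCWGPDEFHPVKVKPYDDGGSYLWGQLNWSRFR
EFDEKGPPSVDQCCDWDWLSMEECAII
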