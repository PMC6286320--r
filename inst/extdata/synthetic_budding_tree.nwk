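((((((((t43:2.098707494,t126:2.098707494):6.737892075,t53:8.836599569):2.340720979,(t65:10.26531382,(t48:7.609059185,((t66:3.765705204,t105:3.765705204):2.359495115,(t83:2.907581752,((t116:0.520429393,t142:0.520429393):1.558830022,t127:2.079259415):0.8283223363):3.217618567):1.483858866):2.656254639):0.912006725):3.097559774,(t104:8.425214292,(t108:4.987347086,((t91:2.188974482,(t125:0.1568177325,t147:0.1568177325):2.032156749):2.64043425,t93:4.829408732):0.1579383536):3.437867206):5.84966603):1.518638065,(t50:7.865899365,(t63:5.098527643,((t88:2.779330833,((t119:1.284940174,t138:1.284940174):0.1840416719,t136:1.468981846):1.310348987):1.810440874,(t101:3.488941888,t109:3.488941888):1.100829819):0.5087559355):2.767371722):7.927619022):7.746452925,(((((t30:0.3929726343,(t143:0.1468796533,t149:0.1468796533):0.246092981):0.9607929166,t137:1.353765551):1.496092449,t118:2.849857999):3.620175402,(t79:4.496482111,t99:4.496482111):1.97355129):16.88500957,(((((t59:3.248835274,t113:3.248835274):0.3606846755,(t107:0.2799708749,t145:0.2799708749):3.329549074):7.209056789,(t98:7.377503738,(t70:4.803791874,t132:4.803791874):2.573711864):3.441072999):1.145061931,t36:11.96363867):5.628355009,((((t20:2.665386221,t120:2.665386221):0.748097857,(t110:3.394262596,(t111:0.1562417584,t148:0.1562417584):3.238020838):0.01922148199):1.229490153,(((t95:0.7680172833,t141:0.7680172833):0.7907716907,t134:1.558788974):0.8538897812,(t122:0.9094404568,t140:0.9094404568):1.503238298):2.230295476):1.615089545,t81:6.258063776):11.3339299):5.76304929):0.184928344):1.742084108,(((t8:6.227535534,t82:6.227535534):3.601620203,(t47:8.624411422,(t55:0.3494249303,t144:0.3494249303):8.274986491):1.204744315):3.692062212,((t74:3.630222567,t106:3.630222567):2.938801897,((t123:2.076696492,(t128:0.1913827407,t146:0.1913827407):1.885313751):1.144813144,t114:3.221509636):3.347514829):6.952193485):11.76083747):1.336552076,((((t7:0.06085111787,t151:0.06085111787):1.752889031,t131:1.813740149):7.531397467,(t84:5.654691087,t85:5.654691087):3.690446529):7.195028013,((((t71:1.665855859,(t133:0.1138375078,t150:0.1138375078):1.552018351):2.799476834,t100:4.465332693):4.646934056,(t52:8.773523296,((t92:7.20612978,t124:7.20612978):1.38426401,t56:8.590393791):0.1831295051):0.3387434533):2.235780687,((t38:3.26720681,t112:3.26720681):3.217543371,(t78:5.051362698,(t89:2.421440869,t121:2.421440869):2.629921829):1.433387484):4.863297255):5.192118192):10.07844187):10.45601756;
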